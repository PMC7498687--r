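#' Construct a feature-by-sample count matrix
#'
#' The common currency of the pipeline: an abundance table of amplicon
#' features (16S ASVs, or KS/AD operational biosynthetic units) across
#' samples, carrying the feature kind and a flag saying whether the counts
#' have been normalized (in which case fractional values are allowed).
#'
#' @param counts numeric matrix, features in rows and samples in columns,
#'   with unique non-empty row and column names. Must be non-negative, and
#'   integer-valued unless `normalized = TRUE`.
#' @param feature_kind one of `"ASV"`, `"OBU_KS"`, `"OBU_AD"`.
#' @param normalized logical; `TRUE` after library-size normalization.
#'
#' @return a `count_matrix` object (a numeric matrix with attributes
#'   `feature_kind` and `normalized`).
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, 2,
#'             dimnames = list(c("f1", "f2"), c("s1", "s2")))
#' count_matrix(m, "ASV")
count_matrix <- function(counts, feature_kind = c("ASV", "OBU_KS", "OBU_AD"),
                         normalized = FALSE) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix")
  }
  fid <- rownames(counts)
  sid <- colnames(counts)
  if (nrow(counts) > 0 && (is.null(fid) || anyDuplicated(fid) || any(fid == ""))) {
    stop("feature ids (rownames) must be unique and non-empty")
  }
  if (ncol(counts) > 0 && (is.null(sid) || anyDuplicated(sid) || any(sid == ""))) {
    stop("sample ids (colnames) must be unique and non-empty")
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and non-missing")
  }
  if (!normalized && any(abs(counts - round(counts)) > 1e-9)) {
    stop("raw (non-normalized) counts must be integers")
  }
  structure(counts, feature_kind = feature_kind, normalized = normalized,
            class = c("count_matrix", class(counts)))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d %s features x %d samples%s\n",
              nrow(x), attr(x, "feature_kind"), ncol(x),
              if (isTRUE(attr(x, "normalized"))) " (normalized)" else ""))
  if (nrow(x) > 0 && ncol(x) > 0) {
    print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))),
                     drop = FALSE])
  }
  invisible(x)
}

#' @rdname count_matrix
#' @param x object to test or access.
#' @export
is_count_matrix <- function(x) inherits(x, "count_matrix")

#' @rdname count_matrix
#' @export
feature_kind <- function(x) attr(x, "feature_kind")

#' @rdname count_matrix
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

# subset while preserving class/attributes (matrix [ drops them)
cm_subset <- function(x, i = NULL, j = NULL) {
  m <- unclass(x)
  if (!is.null(i)) m <- m[i, , drop = FALSE]
  if (!is.null(j)) m <- m[, j, drop = FALSE]
  count_matrix(m, feature_kind = attr(x, "feature_kind"),
               normalized = attr(x, "normalized"))
}
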