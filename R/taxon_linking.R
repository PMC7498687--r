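#' Clean species and OBU tables before link screening
#'
#' Removes sparse low-count features before the regression screen. Under
#' the default `AND` reading a feature is removed when it occurs in at most
#' one sample AND its total reads are below `min_total`; the stricter `OR`
#' reading removes a feature when either condition holds. Sample sets are
#' intersected (and the intersection logged in the report) so both
#' matrices cover identical samples.
#'
#' @param species an ASV [count_matrix()].
#' @param obus an OBU [count_matrix()].
#' @param min_total total-read threshold (default 10).
#' @param combine `"AND"` (default) or `"OR"`.
#' @return list with `species`, `obus` (cleaned), and `report`
#'   (data.frame of removed features and which rule fired, plus the shared
#'   sample set).
#' @export
clean_matrices <- function(species, obus, min_total = 10,
                           combine = c("AND", "OR")) {
  combine <- match.arg(combine)
  shared <- intersect(colnames(species), colnames(obus))
  if (length(shared) < 2) {
    stop("fewer than 2 shared samples; regression is undefined")
  }
  clean_one <- function(m, kind) {
    m <- cm_subset(m, j = shared)
    prev <- rowSums(unclass(m) > 0)
    tot <- rowSums(m)
    sparse <- prev <= 1
    low <- tot < min_total
    removed <- if (combine == "AND") sparse & low else sparse | low
    rule <- ifelse(sparse & low, "sparse+low",
                   ifelse(sparse, "sparse", "low"))
    rep <- data.frame(feature_id = rownames(m)[removed],
                      kind = rep(kind, sum(removed)),
                      prevalence = prev[removed], total = tot[removed],
                      rule = rule[removed], stringsAsFactors = FALSE)
    list(matrix = cm_subset(m, i = !removed), report = rep)
  }
  sp <- clean_one(species, feature_kind(species))
  ob <- clean_one(obus, feature_kind(obus))
  report <- rbind(sp$report, ob$report)
  attr(report, "shared_samples") <- shared
  attr(report, "combine") <- combine
  list(species = sp$matrix, obus = ob$matrix, report = report)
}

#' Remove perfectly collinear species
#'
#' Species whose pairwise Pearson \eqn{r^2} reaches 1 (within a numerical
#' tolerance) are grouped by transitive closure; within each group only
#' the representative with the highest total count is kept (ties broken by
#' lexicographic id). Perfectly collinear duplicates would otherwise yield
#' identical, redundant regressions. Zero-variance species (correlation
#' undefined) form their own group and are removed with reason
#' `"constant"`.
#'
#' @param species a cleaned ASV [count_matrix()].
#' @param r2_tol r-squared at or above which species are merged
#'   (default `1 - 1e-12`).
#' @return list with `species` (deduplicated) and `report` (data.frame of
#'   removed species with their representative and reason).
#' @export
dedup_collinear_species <- function(species, r2_tol = 1 - 1e-12) {
  m <- unclass(species)
  n <- nrow(m)
  if (n == 0) {
    return(list(species = species,
                report = data.frame(species_id = character(),
                                    representative = character(),
                                    reason = character())))
  }
  vars <- apply(m, 1, var)
  constant <- vars == 0
  ids <- rownames(m)

  # union-find over species with r^2 >= tolerance
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  varying <- which(!constant)
  if (length(varying) > 1) {
    cm <- suppressWarnings(cor(t(m[varying, , drop = FALSE])))
    for (a in seq_along(varying)) {
      for (b in seq_len(a - 1L)) {
        if (!is.na(cm[a, b]) && cm[a, b]^2 >= r2_tol) {
          ra <- find(varying[a]); rb <- find(varying[b])
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))

  keep <- rep(FALSE, n)
  rep_of <- character(n)
  for (g in unique(root[!constant])) {
    members <- which(root == g & !constant)
    tot <- rowSums(m[members, , drop = FALSE])
    best <- members[order(-tot, ids[members], method = "radix")][1]
    keep[best] <- TRUE
    rep_of[members] <- ids[best]
  }
  dropped <- !keep & !constant
  report <- rbind(
    data.frame(species_id = ids[dropped],
               representative = rep_of[dropped],
               reason = rep("collinear", sum(dropped)),
               stringsAsFactors = FALSE),
    data.frame(species_id = ids[constant],
               representative = rep(NA_character_, sum(constant)),
               reason = rep("constant", sum(constant)),
               stringsAsFactors = FALSE))
  list(species = cm_subset(species, i = keep), report = report)
}

#' Fit one no-intercept link between an OBU and a species
#'
#' The model is \eqn{OBU_i = \alpha_{i,j} \, species_j} with no intercept,
#' reflecting the assumption that a biosynthetic domain encoded on a
#' producer's chromosome co-occurs linearly with its 16S gene. Closed
#' forms: \eqn{\hat\alpha = \sum xy / \sum x^2}, residual variance
#' \eqn{s^2 = \sum (y - \hat\alpha x)^2 / df},
#' \eqn{SE = \sqrt{s^2 / \sum x^2}}, \eqn{t = \hat\alpha / SE}, two-sided p
#' from Student's t. The no-intercept \eqn{r^2} convention is
#' \eqn{1 - \sum (y - \hat\alpha x)^2 / \sum y^2}.
#'
#' @param obu_counts,species_counts equal-length per-sample vectors
#'   (`n >= 2`); the species vector must not be all zero.
#' @param df_convention `"n_minus_1"` (default) or `"n"`; software differs
#'   on the residual degrees of freedom of a one-parameter no-intercept
#'   fit.
#' @param obu_id,species_id optional labels carried into the record.
#' @return a one-row data.frame (`obu_id`, `species_id`, `alpha_hat`,
#'   `t_stat`, `p_value`, `n_samples`, `r2`).
#' @export
fit_link <- function(obu_counts, species_counts,
                     df_convention = c("n_minus_1", "n"),
                     obu_id = NA_character_, species_id = NA_character_) {
  df_convention <- match.arg(df_convention)
  x <- as.numeric(species_counts)
  y <- as.numeric(obu_counts)
  n <- length(x)
  if (length(y) != n) stop("vectors must have equal length")
  if (n < 2) stop("need at least 2 samples")
  sxx <- sum(x^2)
  if (sxx == 0) stop("all-zero species vector; slope undefined")
  df <- if (df_convention == "n_minus_1") n - 1L else n
  alpha <- sum(x * y) / sxx
  rss <- max(sum((y - alpha * x)^2), 0)
  s2 <- rss / df
  tval <- if (s2 == 0) sign(alpha) * Inf else alpha / sqrt(s2 / sxx)
  p <- 2 * pt(-abs(tval), df)
  p <- max(p, .Machine$double.xmin)  # underflow-safe minimum
  syy <- sum(y^2)
  data.frame(obu_id = obu_id, species_id = species_id, alpha_hat = alpha,
             t_stat = tval, p_value = p, n_samples = n,
             r2 = if (syy > 0) 1 - rss / syy else NA_real_,
             stringsAsFactors = FALSE)
}

#' Screen all OBU-by-species pairs with no-intercept regressions
#'
#' Fits every (OBU, species) pair with [fit_link()]'s closed forms
#' (vectorized over the full cross) and retains records below the p-value
#' threshold, sorted by OBU id and then p. No multiple-testing correction
#' is applied -- the screen is a fixed p cutoff -- but the total number of
#' tests is reported in the `n_tests` attribute so users can correct on
#' their own. All-zero species columns are skipped with a reason (in the
#' `skipped_species` attribute).
#'
#' @param species,obus cleaned, deduplicated [count_matrix()] objects on a
#'   common scale (normalized per 100,000 by default upstream; raw counts
#'   also work -- the slope simply changes units). Plain numeric matrices
#'   with dimnames are accepted too, e.g. for centered or residual data.
#' @param p_threshold retention threshold (default 0.001).
#' @param df_convention passed to the closed forms (see [fit_link()]).
#' @return data.frame of retained link records with attributes `n_tests`
#'   and `skipped_species`.
#' @export
screen_links <- function(species, obus, p_threshold = 0.001,
                         df_convention = c("n_minus_1", "n")) {
  df_convention <- match.arg(df_convention)
  if (!identical(colnames(species), colnames(obus))) {
    stop("species and OBU matrices must cover identical samples in order")
  }
  empty <- data.frame(obu_id = character(), species_id = character(),
                      alpha_hat = numeric(), t_stat = numeric(),
                      p_value = numeric(), n_samples = integer(),
                      r2 = numeric(), stringsAsFactors = FALSE)
  if (nrow(obus) == 0 || nrow(species) == 0) {
    attr(empty, "n_tests") <- 0L
    attr(empty, "skipped_species") <- character(0)
    return(empty)
  }
  X <- t(unclass(species))  # samples x species
  Y <- t(unclass(obus))     # samples x obus
  n <- nrow(X)
  df <- if (df_convention == "n_minus_1") n - 1L else n
  sxx <- colSums(X^2)
  skipped <- colnames(X)[sxx == 0]
  ok <- sxx > 0
  X <- X[, ok, drop = FALSE]
  sxx <- sxx[ok]
  syy <- colSums(Y^2)
  sxy <- crossprod(X, Y)                      # species x obus
  alpha <- sxy / sxx
  rss <- pmax(sweep(-sxy^2 / sxx, 2, syy, "+"), 0)
  s2 <- rss / df
  tval <- ifelse(s2 == 0, sign(alpha) * Inf, alpha / sqrt(s2 / sxx))
  p <- pmax(2 * pt(-abs(tval), df), .Machine$double.xmin)
  r2 <- 1 - sweep(rss, 2, ifelse(syy > 0, syy, NA_real_), "/")

  hit <- which(p < p_threshold, arr.ind = TRUE)
  out <- if (nrow(hit)) {
    data.frame(obu_id = colnames(Y)[hit[, 2]],
               species_id = rownames(sxy)[hit[, 1]],
               alpha_hat = alpha[hit], t_stat = tval[hit],
               p_value = p[hit], n_samples = n, r2 = r2[hit],
               stringsAsFactors = FALSE)
  } else empty
  out <- out[order(out$obu_id, out$p_value, out$species_id,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tests") <- length(p)
  attr(out, "skipped_species") <- skipped
  out
}

#' Summarize linked OBUs per genus
#'
#' Aggregates screened links to the genus level: each genus gets the union
#' of OBU ids linked to any of its member species (an OBU linked to two
#' congeneric species counts once) and its mean relative abundance across
#' samples. Genera with zero links are included with `n_linked_obus = 0`,
#' matching bubble-plot conventions where linkless genera are still drawn.
#'
#' @param links data.frame from [screen_links()].
#' @param taxonomy taxonomy data.frame covering every linked species.
#' @param species_matrix the species [count_matrix()] the links were
#'   screened on (relative abundances are computed from it).
#' @return data.frame with `genus`, `order`, `mean_rel_abundance`,
#'   `n_linked_obus`, and a comma-separated `obu_ids` column.
#' @export
summarize_by_genus <- function(links, taxonomy, species_matrix) {
  miss <- setdiff(links$species_id, taxonomy$feature_id)
  if (length(miss)) {
    stop("species missing from taxonomy: ", paste(miss, collapse = ", "))
  }
  tax <- taxonomy[match(rownames(species_matrix), taxonomy$feature_id), ]
  if (anyNA(tax$feature_id)) {
    stop("species missing from taxonomy: ",
         rownames(species_matrix)[which(is.na(tax$feature_id))[1]])
  }
  rel <- sweep(unclass(species_matrix), 2, colSums(species_matrix), "/")
  sp_mean_rel <- rowMeans(rel)

  genera <- unique(tax$genus)
  rows <- lapply(genera, function(g) {
    members <- tax$feature_id[tax$genus == g]
    obu_ids <- sort(unique(links$obu_id[links$species_id %in% members]))
    data.frame(genus = g, order = tax$order[tax$genus == g][1],
               mean_rel_abundance = sum(sp_mean_rel[members]),
               n_linked_obus = length(obu_ids),
               obu_ids = paste(obu_ids, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$mean_rel_abundance, out$genus, method = "radix"), ,
      drop = FALSE]
}

#' Regress genus abundance against linked-OBU count
#'
#' Ordinary least squares (with intercept) of the number of linked OBUs on
#' mean relative abundance across genera. A near-zero \eqn{r^2} means
#' taxonomic abundance does not predict biosynthetic potential -- the
#' low-abundance, OBU-rich taxa signature.
#'
#' @param summaries data.frame from [summarize_by_genus()] (>= 3 genera).
#' @return list with `r2`, `slope`, `p_value`, `n_genera`.
#' @export
abundance_vs_potential <- function(summaries) {
  if (nrow(summaries) < 3) stop("need at least 3 genera for the regression")
  if (var(summaries$mean_rel_abundance) == 0) {
    stop("zero variance in genus abundance; regression undefined")
  }
  fit <- lm(n_linked_obus ~ mean_rel_abundance, data = summaries)
  sm <- summary(fit)
  list(r2 = sm$r.squared, slope = coef(fit)[["mean_rel_abundance"]],
       p_value = sm$coefficients["mean_rel_abundance", "Pr(>|t|)"],
       n_genera = nrow(summaries))
}
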