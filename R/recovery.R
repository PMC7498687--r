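#' OBU recovery of the cultured fraction
#'
#' Compares OBU presence between environmental DNA (eDNA) and plate-derived
#' DNA (pDNA) tables that share one OBU id namespace (i.e. come from a
#' single pooled clustering run). Presence is count at or above
#' `min_count` in any pooled sample; recovery is the percentage of eDNA
#' OBUs also found in the pDNA, which makes it invariant to sequencing
#' depth. OBUs found only in the cultured fraction are counted too.
#'
#' @param edna,pdna OBU [count_matrix()] objects on one id namespace.
#' @param min_count presence threshold (default 1, i.e. any read after
#'   singleton removal).
#' @param domain,source labels carried into the report.
#' @return one-row data.frame: `domain`, `source`, `n_obus_edna`,
#'   `n_obus_pdna`, `n_shared`, `pct_recovered`, `n_pdna_only`.
#' @export
obu_recovery <- function(edna, pdna, min_count = 1,
                         domain = feature_kind(edna), source = NA_character_) {
  e_ids <- rownames(edna)[rowSums(unclass(edna) >= min_count) > 0]
  p_ids <- rownames(pdna)[rowSums(unclass(pdna) >= min_count) > 0]
  if (length(e_ids) && length(p_ids) && !length(intersect(e_ids, p_ids))) {
    pre <- function(x) unique(sub("[0-9]+$", "", x))
    if (!length(intersect(pre(e_ids), pre(p_ids)))) {
      warning("no shared OBU ids and different id prefixes: were the two ",
              "tables produced by the same pooled clustering run?")
    }
  }
  shared <- length(intersect(e_ids, p_ids))
  data.frame(domain = domain, source = source,
             n_obus_edna = length(e_ids), n_obus_pdna = length(p_ids),
             n_shared = shared,
             pct_recovered = if (length(e_ids)) 100 * shared / length(e_ids)
                             else NA_real_,
             n_pdna_only = length(setdiff(p_ids, e_ids)),
             stringsAsFactors = FALSE)
}

#' OBU recovery grouped by a metadata field
#'
#' Pools samples of each group (e.g. isolation source) in both tables and
#' computes one recovery report per group.
#'
#' @param edna,pdna OBU [count_matrix()] objects (one id namespace).
#' @param metadata sample metadata covering both tables' samples.
#' @param pool_by metadata column to group by (default `"source"`).
#' @param min_count presence threshold per pooled group.
#' @return data.frame with one row per group.
#' @export
obu_recovery_by <- function(edna, pdna, metadata, pool_by = "source",
                            min_count = 1) {
  check_metadata_cover(edna, metadata)
  check_metadata_cover(pdna, metadata)
  groups <- unique(metadata[[pool_by]][metadata$sample_id %in%
                                         c(colnames(edna), colnames(pdna))])
  rows <- lapply(groups, function(g) {
    gs <- metadata$sample_id[metadata[[pool_by]] == g]
    es <- intersect(colnames(edna), gs)
    ps <- intersect(colnames(pdna), gs)
    if (!length(es) || !length(ps)) return(NULL)
    obu_recovery(cm_subset(edna, j = es), cm_subset(pdna, j = ps),
                 min_count = min_count, source = g)
  })
  do.call(rbind, rows)
}

#' Culturability estimate
#'
#' The culturable fraction of a community: colony-forming units as a
#' percentage of the total (microscopy-stained) direct cell count, both
#' per the same unit of sample material.
#'
#' @param cfu colony-forming units per unit (vectorized over samples).
#' @param direct_counts direct microscopy counts per the same unit.
#' @param sample_id optional labels.
#' @return data.frame with `sample_id`, `cfu_per_unit`,
#'   `direct_count_per_unit`, `pct_culturable`.
#' @export
culturability <- function(cfu, direct_counts, sample_id = NULL) {
  if (length(cfu) != length(direct_counts)) {
    stop("cfu and direct_counts must have equal length")
  }
  if (any(direct_counts <= 0)) stop("direct counts must be positive")
  if (any(cfu < 0)) stop("CFU counts must be non-negative")
  if (is.null(sample_id)) sample_id <- as.character(seq_along(cfu))
  data.frame(sample_id = sample_id, cfu_per_unit = cfu,
             direct_count_per_unit = direct_counts,
             pct_culturable = 100 * cfu / direct_counts,
             stringsAsFactors = FALSE)
}
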