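#' Reverse complement of a DNA sequence
#'
#' Standard complement over A/C/G/T with N mapping to N.
#'
#' @param x character vector of DNA sequences.
#' @return reverse-complemented sequences.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", toupper(x))
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Pairwise sequence identity under the clustering metric
#'
#' Global Needleman-Wunsch alignment (match +1, mismatch -1, gap -2, with
#' terminal gaps penalised like internal ones); identity is matches over
#' alignment columns, excluding any column containing `N` from both
#' numerator and denominator. The N rule keeps the single-N spacer used
#' when joining read pairs from penalising otherwise identical sequences.
#' Terminal gaps are not free: combined with the N/terminal-column
#' exclusion a free-end-gap alignment would let a short perfect dovetail
#' overlap between unrelated sequences masquerade as identity 1 and
#' collapse distinct clusters; the pipeline's joined reads share one fixed
#' length, so penalised end gaps cost nothing on genuine comparisons.
#'
#' @param a,b DNA sequences (single strings).
#' @return identity in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  .nw_identity_cpp(toupper(a), toupper(b))
}

#' Trim read pairs to fixed lengths
#'
#' Forward and reverse reads are truncated (from the 3' end) to 240 bp and
#' 175 bp by default; pairs in which either read is shorter than its target
#' are discarded and counted, since downstream joining assumes fixed
#' lengths.
#'
#' @param pairs data.frame with columns `read_id`, `sample_id`, `forward`,
#'   `reverse`.
#' @param fwd_len,rev_len target lengths in bp.
#' @return list with `pairs` (trimmed) and `n_discarded`.
#' @export
trim_pairs <- function(pairs, fwd_len = 240, rev_len = 175) {
  need <- c("read_id", "sample_id", "forward", "reverse")
  miss <- setdiff(need, colnames(pairs))
  if (length(miss)) stop("pairs missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(pairs$read_id)) stop("duplicated read ids in pairs")
  keep <- nchar(pairs$forward) >= fwd_len & nchar(pairs$reverse) >= rev_len
  out <- pairs[keep, , drop = FALSE]
  out$forward <- substr(out$forward, 1, fwd_len)
  out$reverse <- substr(out$reverse, 1, rev_len)
  list(pairs = out, n_discarded = sum(!keep))
}

#' Join a trimmed read pair with a single-N spacer
#'
#' The joined sequence is trimmed-forward + `"N"` + reverse-complement of
#' the trimmed reverse read; with default trimming its length is
#' 240 + 1 + 175 = 416 bp.
#'
#' @param forward,reverse trimmed sequences (vectorized).
#' @return joined sequences.
#' @export
join_pairs <- function(forward, reverse) {
  if (any(nchar(forward) == 0) || any(nchar(reverse) == 0)) {
    stop("cannot join empty reads (discard at trimming)")
  }
  paste0(toupper(forward), "N", reverse_complement(reverse))
}

#' Greedy centroid clustering at an identity threshold
#'
#' Inputs are sorted by abundance weight descending (ties broken
#' lexicographically by sequence, then id -- a total order, so clustering
#' is invariant to input order); each item joins the first existing
#' centroid whose identity (see [seq_identity()]) meets the threshold, or
#' founds a new cluster. An optional shared 8-mer prefilter skips
#' alignments that provably cannot reach the threshold; it never changes
#' the result.
#'
#' @param sequences character vector of sequences.
#' @param ids item ids (default positional).
#' @param weights abundance weights (reads carry 1; round-1 centroids carry
#'   their member counts).
#' @param threshold identity threshold in `(0, 1]`.
#' @param prefilter enable the conservative 8-mer prefilter.
#' @return list of clusters, each `list(centroid_id, centroid, member_ids,
#'   member_weights, total_weight)`.
#' @export
cluster_greedy <- function(sequences, ids = NULL, weights = NULL,
                           threshold = 0.95, prefilter = FALSE) {
  if (threshold <= 0 || threshold > 1) {
    stop("identity threshold must lie in (0, 1]")
  }
  n <- length(sequences)
  if (n == 0) return(list())
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(ids) == n, length(weights) == n)
  sequences <- toupper(sequences)

  ord <- order(-weights, sequences, ids, method = "radix")
  centroid_seq <- character(0)
  centroid_kmers <- list()
  clusters <- list()

  for (i in ord) {
    s <- sequences[i]
    assigned <- 0L
    km <- if (prefilter) kmer_set(s) else NULL
    for (c in seq_along(clusters)) {
      if (prefilter &&
          skip_by_kmers(km, centroid_kmers[[c]], nchar(s),
                        nchar(centroid_seq[c]), threshold)) next
      if (seq_identity(s, centroid_seq[c]) >= threshold) {
        assigned <- c
        break
      }
    }
    if (assigned > 0L) {
      cl <- clusters[[assigned]]
      cl$member_ids <- c(cl$member_ids, ids[i])
      cl$member_weights <- c(cl$member_weights, weights[i])
      cl$total_weight <- cl$total_weight + weights[i]
      clusters[[assigned]] <- cl
    } else {
      clusters[[length(clusters) + 1L]] <- list(
        centroid_id = ids[i], centroid = s, member_ids = ids[i],
        member_weights = weights[i], total_weight = weights[i])
      centroid_seq <- c(centroid_seq, s)
      if (prefilter) centroid_kmers[[length(clusters)]] <- km
    }
  }
  clusters
}

kmer_set <- function(s, k = 8L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

# skip only when shared 8-mers are below a conservative lower bound implied
# by identity >= threshold; generous slack so the prefilter is semantics-free
skip_by_kmers <- function(km_a, km_b, la, lb, threshold, k = 8L) {
  lmin <- min(la, lb)
  lmax <- max(la, lb)
  max_edits <- floor((1 - threshold) * lmax) + abs(la - lb) + k
  bound <- lmin - (k - 1L) - k * max_edits
  if (bound <= 0) return(FALSE)
  length(intersect(km_a, km_b)) < bound
}

#' Two-round OBU clustering pipeline
#'
#' The full domain-amplicon processing chain: fixed-length trimming,
#' single-N joining, within-sample greedy clustering at 97% identity, an
#' optional chimera-checking hook over the round-1 clusters (a pass-through
#' by default), pooled clustering of the round-1 centroids at 95% identity
#' with member counts as abundance weights, and removal of clusters whose
#' total pooled member count is a single read. The surviving 95% clusters
#' are the operational biosynthetic units (OBUs); the returned table counts
#' each sample's reads per OBU.
#'
#' @param pairs data.frame of read pairs (`read_id`, `sample_id`,
#'   `forward`, `reverse`); all samples share one domain kind.
#' @param domain `"KS"` or `"AD"`.
#' @param fwd_len,rev_len trim targets (defaults 240/175 bp).
#' @param id1 within-sample identity threshold (default 0.97).
#' @param id2 pooled identity threshold (default 0.95).
#' @param min_cluster_reads minimum total member reads for an OBU to be
#'   kept (default 2: singletons discarded). Set 1 to keep singletons.
#' @param chimera_hook function over the per-sample round-1 cluster list;
#'   the default passes clusters through unchanged (de novo chimera
#'   detection is delegated to external tools).
#' @param prefilter passed to [cluster_greedy()].
#' @return list with `counts` (OBU [count_matrix()]), `clusters` (final
#'   clusters with per-sample counts and member read ids) and `discards`
#'   (`trimmed`, `singleton_reads`).
#' @export
run_obu_pipeline <- function(pairs, domain = c("KS", "AD"),
                             fwd_len = 240, rev_len = 175,
                             id1 = 0.97, id2 = 0.95,
                             min_cluster_reads = 2,
                             chimera_hook = identity,
                             prefilter = FALSE) {
  domain <- match.arg(domain)
  kind <- paste0("OBU_", domain)
  all_samples <- unique(pairs$sample_id)
  if (nrow(pairs) == 0) {
    warning("no input read pairs; returning an empty OBU table")
    return(list(counts = count_matrix(
      matrix(0L, 0, 0, dimnames = list(character(), character())), kind),
      clusters = list(),
      discards = list(trimmed = 0L, singleton_reads = 0L)))
  }

  tr <- trim_pairs(pairs, fwd_len, rev_len)
  kept <- tr$pairs
  kept$joined <- if (nrow(kept)) join_pairs(kept$forward, kept$reverse)
                 else character(0)

  # round 1: within-sample clustering of joined reads at id1
  r1 <- list()
  for (s in unique(kept$sample_id)) {
    sub <- kept[kept$sample_id == s, , drop = FALSE]
    cls <- cluster_greedy(sub$joined, ids = sub$read_id,
                          threshold = id1, prefilter = prefilter)
    cls <- chimera_hook(cls)
    for (cl in cls) {
      cl$sample_id <- s
      cl$round <- "within_sample"
      r1[[length(r1) + 1L]] <- cl
    }
  }

  # round 2: pooled clustering of round-1 centroids at id2, weighted by
  # their member read counts
  if (length(r1)) {
    r1_ids <- sprintf("r1_%05d", seq_along(r1))
    cls2 <- cluster_greedy(
      vapply(r1, `[[`, character(1), "centroid"), ids = r1_ids,
      weights = vapply(r1, function(cl) sum(cl$member_weights), numeric(1)),
      threshold = id2, prefilter = prefilter)
  } else cls2 <- list()

  # assemble final clusters with per-sample read counts
  final <- lapply(cls2, function(cl) {
    idx <- match(cl$member_ids, sprintf("r1_%05d", seq_along(r1)))
    member_reads <- unlist(lapply(r1[idx], `[[`, "member_ids"),
                           use.names = FALSE)
    per_sample <- vapply(all_samples, function(s) {
      sum(vapply(r1[idx], function(m) {
        if (m$sample_id == s) length(m$member_ids) else 0L
      }, integer(1)))
    }, integer(1))
    list(centroid = cl$centroid, per_sample = per_sample,
         member_read_ids = member_reads, total = sum(per_sample),
         round = "pooled")
  })

  totals <- vapply(final, `[[`, numeric(1), "total")
  singleton <- totals < min_cluster_reads
  n_singleton_reads <- sum(totals[singleton])
  final <- final[!singleton]

  # stable OBU ids: by total abundance descending, ties by centroid sequence
  if (length(final)) {
    ord <- order(-vapply(final, `[[`, numeric(1), "total"),
                 vapply(final, `[[`, character(1), "centroid"),
                 method = "radix")
    final <- final[ord]
    for (i in seq_along(final)) {
      final[[i]]$obu_id <- sprintf("OBU_%s_%04d", domain, i)
    }
    m <- do.call(rbind, lapply(final, `[[`, "per_sample"))
    storage.mode(m) <- "integer"
    dimnames(m) <- list(vapply(final, `[[`, character(1), "obu_id"),
                        all_samples)
  } else {
    m <- matrix(0L, 0, length(all_samples),
                dimnames = list(character(), all_samples))
  }

  list(counts = count_matrix(m, kind), clusters = final,
       discards = list(trimmed = tr$n_discarded,
                       singleton_reads = as.integer(n_singleton_reads)))
}
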