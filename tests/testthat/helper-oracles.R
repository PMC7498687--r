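# Independent reference implementations used as oracles. These stay
# deliberately naive (explicit loops, full matrices) and separate from the
# package's code paths.

# pure-R global Needleman-Wunsch identity under the package's scoring
# (match +1, mismatch -1, gap -2, N columns excluded); same deterministic
# tie-break order (diagonal, up, left)
ref_nw_identity <- function(a, b) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  m <- length(A); n <- length(B)
  if (m == 0 || n == 0) return(0)
  H <- matrix(0, m + 1, n + 1)
  P <- matrix(0L, m + 1, n + 1)
  H[, 1] <- -2 * (0:m); H[1, ] <- -2 * (0:n)
  P[, 1] <- 2L; P[1, ] <- 3L; P[1, 1] <- 0L
  for (i in 1:m) {
    for (j in 1:n) {
      s <- if (A[i] == B[j]) 1 else -1
      cand <- c(H[i, j] + s, H[i, j + 1] - 2, H[i + 1, j] - 2)
      k <- which.max(cand)
      H[i + 1, j + 1] <- cand[k]
      P[i + 1, j + 1] <- k
    }
  }
  i <- m + 1; j <- n + 1; matches <- 0; cols <- 0
  while (i > 1 || j > 1) {
    k <- P[i, j]
    if (k == 1L) {
      if (A[i - 1] != "N" && B[j - 1] != "N") {
        cols <- cols + 1
        if (A[i - 1] == B[j - 1]) matches <- matches + 1
      }
      i <- i - 1; j <- j - 1
    } else if (k == 2L) {
      if (A[i - 1] != "N") cols <- cols + 1
      i <- i - 1
    } else {
      if (B[j - 1] != "N") cols <- cols + 1
      j <- j - 1
    }
  }
  if (cols == 0) 0 else matches / cols
}

# all-pairs reference clustering: scores the full identity matrix first,
# then assigns greedily in the same total order as the production engine
ref_cluster_allpairs <- function(sequences, ids = NULL, weights = NULL,
                                 threshold) {
  n <- length(sequences)
  if (n == 0) return(list())
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (is.null(weights)) weights <- rep(1, n)
  sequences <- toupper(sequences)
  idm <- matrix(1, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) idm[i, j] <- idm[j, i] <- seq_identity(sequences[i],
                                                        sequences[j])
    }
  }
  ord <- order(-weights, sequences, ids, method = "radix")
  centroid_idx <- integer(0)
  membership <- integer(n)
  for (i in ord) {
    hit <- 0L
    for (c in centroid_idx) {
      if (idm[i, c] >= threshold) { hit <- c; break }
    }
    if (hit > 0L) {
      membership[i] <- hit
    } else {
      centroid_idx <- c(centroid_idx, i)
      membership[i] <- i
    }
  }
  split(ids, ids[membership])
}

# membership partition of a cluster_greedy result, for comparison with the
# reference and with planted truth (label-free)
partition_of <- function(clusters) {
  lapply(clusters, function(cl) sort(cl$member_ids))
}
same_partition <- function(p1, p2) {
  key <- function(p) unname(sort(vapply(p, paste, character(1),
                                        collapse = "|")))
  identical(key(p1), key(p2))
}

# random DNA helpers
rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
mutate_dna <- function(seq, n_sub) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(chars), n_sub)
  for (i in pos) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

# random small count matrix for round-trip properties
rand_count_matrix <- function(nf = 5, ns = 3, kind = "ASV") {
  m <- matrix(rpois(nf * ns, 20), nf, ns,
              dimnames = list(sprintf("f%02d", seq_len(nf)),
                              sprintf("s%02d", seq_len(ns))))
  storage.mode(m) <- "integer"
  count_matrix(m, kind)
}

# all permutations of a vector (for exhaustive PERMANOVA p at tiny N)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(all_perms(v[-i]), function(p) c(v[i], p))
  }))
}

# small two-group Euclidean distance fixture
rand_dist <- function(n = 8, sep = 0) {
  pts <- matrix(rnorm(n * 2), n, 2)
  pts[seq_len(n / 2), 1] <- pts[seq_len(n / 2), 1] + sep
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  d
}
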