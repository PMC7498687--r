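#' Chao1 richness estimate for one sample
#'
#' Nonparametric richness estimation from singleton and doubleton counts.
#' The bias-corrected form (default) is
#' \deqn{S_{chao1} = S_{obs} + \frac{f_1 (f_1 - 1)}{2 (f_2 + 1)}}
#' where \eqn{f_1} and \eqn{f_2} are the numbers of features observed
#' exactly once and twice; the classic form \eqn{S_{obs} + f_1^2 / (2 f_2)}
#' is available. Standard errors come from the usual asymptotic variance
#' formulas for the chosen variant. The estimator is only defined on raw
#' integer counts; normalized data are rejected.
#'
#' @param counts non-negative integer vector of feature counts for one
#'   sample.
#' @param bias_corrected use the bias-corrected variant (default).
#' @param sample_id optional label carried into the result.
#' @return list with `sample_id`, `observed_S`, `chao1`, `chao1_se`, `f1`,
#'   `f2`.
#' @export
chao1 <- function(counts, bias_corrected = TRUE, sample_id = NA_character_) {
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-9)) {
    stop("Chao1 requires raw integer counts; it is undefined on normalized data")
  }
  counts <- round(counts)
  S <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)

  if (bias_corrected) {
    est <- S + f1 * (f1 - 1) / (2 * (f2 + 1))
    v <- if (f1 == 0) 0
    else if (f2 > 0) {
      f1 * (f1 - 1) / (2 * (f2 + 1)) +
        f1 * (2 * f1 - 1)^2 / (4 * (f2 + 1)^2) +
        f1^2 * f2 * (f1 - 1)^2 / (4 * (f2 + 1)^4)
    } else {
      f1 * (f1 - 1) / 2 + f1 * (2 * f1 - 1)^2 / 4 - f1^4 / (4 * est)
    }
  } else {
    if (f2 > 0) {
      est <- S + f1^2 / (2 * f2)
      r <- f1 / f2
      v <- f2 * (r^2 / 2 + r^3 + r^4 / 4)
    } else {
      # classic form is undefined at f2 = 0; standard fallback
      est <- S + f1 * (f1 - 1) / 2
      v <- if (f1 == 0) 0
           else f1 * (f1 - 1) / 2 + f1 * (2 * f1 - 1)^2 / 4 - f1^4 / (4 * est)
    }
  }
  list(sample_id = sample_id, observed_S = S, chao1 = est,
       chao1_se = sqrt(max(v, 0)), f1 = f1, f2 = f2)
}

#' Chao1 across all samples of a count matrix
#'
#' @param matrix a raw [count_matrix()].
#' @param bias_corrected passed to [chao1()].
#' @return data.frame with one row per sample.
#' @export
chao1_table <- function(matrix, bias_corrected = TRUE) {
  rows <- lapply(colnames(matrix), function(s) {
    as.data.frame(chao1(unclass(matrix)[, s], bias_corrected, sample_id = s))
  })
  do.call(rbind, rows)
}

#' Expected rarefaction curve (closed form)
#'
#' Expected number of features observed in a random subsample of size `n`
#' without replacement:
#' \deqn{E[S_n] = \sum_i \left[1 - \binom{N - N_i}{n} / \binom{N}{n}\right]}
#' evaluated with log-gamma arithmetic for numerical stability.
#'
#' @param counts non-negative integer counts for one sample.
#' @param depths subsample sizes, each `<=` the sample total.
#' @return data.frame with columns `depth` and `expected_richness`.
#' @export
rarefaction_curve <- function(counts, depths) {
  if (any(counts < 0)) stop("counts must be non-negative")
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (any(depths > N)) {
    stop("rarefaction depth exceeds the sample total (", N, ")")
  }
  if (any(depths < 0)) stop("depths must be non-negative")
  es <- vapply(depths, function(n) {
    sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
  }, numeric(1))
  data.frame(depth = depths, expected_richness = es)
}

#' Normalize a count matrix to a common library size
#'
#' `total_sum` scales every column so it sums exactly to `target`
#' (fractional values allowed); `rarefy` subsamples each column to `target`
#' reads without replacement (multivariate hypergeometric, seeded), and
#' drops columns whose total is below `target` with a warning.
#'
#' @param matrix a [count_matrix()] with positive column sums.
#' @param target per-sample total after normalization (default 100000).
#' @param method `"total_sum"` or `"rarefy"`.
#' @param seed seed for the rarefying draw.
#' @return a normalized [count_matrix()].
#' @export
normalize_counts <- function(matrix, target = 100000,
                             method = c("total_sum", "rarefy"), seed = 1) {
  method <- match.arg(method)
  tot <- colSums(matrix)
  if (any(tot == 0)) {
    stop("sample with zero total count: ",
         colnames(matrix)[which(tot == 0)[1]])
  }
  if (method == "total_sum") {
    m <- sweep(unclass(matrix), 2, tot / target, "/")
    return(count_matrix(m, feature_kind = feature_kind(matrix),
                        normalized = TRUE))
  }
  shallow <- tot < target
  if (any(shallow)) {
    warning("dropping samples below the rarefaction depth: ",
            paste(colnames(matrix)[shallow], collapse = ", "))
  }
  m <- unclass(matrix)[, !shallow, drop = FALSE]
  with_rng(substream_seed(seed, "rarefy"), {
    for (j in seq_len(ncol(m))) {
      m[, j] <- hypergeom_subsample(m[, j], target)
    }
  })
  storage.mode(m) <- "integer"
  count_matrix(m, feature_kind = feature_kind(matrix), normalized = TRUE)
}

# sequential conditional hypergeometric draw of `n` reads from counts `x`
hypergeom_subsample <- function(x, n) {
  out <- numeric(length(x))
  remaining <- sum(x)
  need <- n
  for (i in seq_along(x)) {
    if (need == 0) break
    k <- rhyper(1, x[i], remaining - x[i], need)
    out[i] <- k
    remaining <- remaining - x[i]
    need <- need - k
  }
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' \deqn{d(x, y) = 1 - \frac{2 \sum_i \min(x_i, y_i)}{\sum_i x_i + \sum_i y_i}}
#' computed between every pair of samples (columns).
#'
#' @param matrix a [count_matrix()] with at least two samples, none with a
#'   zero total.
#' @return symmetric dissimilarity matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
bray_curtis <- function(matrix) {
  if (ncol(matrix) < 2) stop("Bray-Curtis needs at least 2 samples")
  tot <- colSums(matrix)
  if (any(tot == 0)) {
    stop("sample with zero total count: ",
         colnames(matrix)[which(tot == 0)[1]])
  }
  m <- unclass(matrix)
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <-
        1 - 2 * sum(pmin(m[, i], m[, j])) / (tot[i] + tot[j])
    }
  }
  d
}

#' Principal coordinates analysis
#'
#' Gower double-centering of \eqn{-\tfrac{1}{2} d^2} followed by
#' eigendecomposition. Axes with eigenvalues above a small positive
#' tolerance are kept; coordinates are eigenvectors scaled by the square
#' root of their eigenvalues. Negative eigenvalues (non-Euclidean
#' distances) are reported, not corrected. Eigenvector signs are fixed so
#' the largest-magnitude coordinate on each axis is positive, making
#' results reproducible across platforms.
#'
#' @param dist symmetric dissimilarity matrix with zero diagonal.
#' @return list with `coordinates` (samples x kept axes), `eigenvalues`
#'   (all, descending), `prop_var` (share of the positive eigenvalue sum
#'   per kept axis).
#' @export
pcoa <- function(dist) {
  dist <- as.matrix(dist)
  if (!isTRUE(all.equal(dist, t(dist))) || any(diag(dist) != 0)) {
    stop("`dist` must be symmetric with a zero diagonal")
  }
  n <- nrow(dist)
  A <- -0.5 * dist^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values), 0) * 1e-8
  keep <- which(e$values > tol)
  coords <- e$vectors[, keep, drop = FALSE]
  rownames(coords) <- rownames(dist)
  if (length(keep)) {
    for (k in seq_along(keep)) {
      v <- coords[, k]
      if (v[which.max(abs(v))] < 0) v <- -v
      coords[, k] <- v * sqrt(e$values[keep[k]])
    }
    colnames(coords) <- paste0("Axis", seq_along(keep))
  }
  pos_sum <- sum(e$values[e$values > 0])
  list(coordinates = coords, eigenvalues = e$values,
       prop_var = if (pos_sum > 0) e$values[keep] / pos_sum else numeric(0))
}

#' Correlation-based biplot loadings for an ordination
#'
#' The loading of feature `f` on axis `k` is the Pearson correlation of
#' `f`'s abundance profile with the axis-`k` sample coordinates, scaled by
#' the ratio of that axis's coordinate standard deviation to the first
#' axis's, so later (lower-variance) axes carry proportionally smaller
#' loadings. Features whose maximum absolute loading exceeds the cutoff
#' are flagged (the convention used to label influential OBUs on
#' ordination plots). Constant features get zero loadings.
#'
#' @param matrix the (normalized) [count_matrix()] the ordination came from.
#' @param ordination result of [pcoa()] on the same samples.
#' @param magnitude_cutoff flagging threshold (default 0.1).
#' @return list with `loadings` (features x axes) and `flagged` feature
#'   ids.
#' @export
biplot_loadings <- function(matrix, ordination, magnitude_cutoff = 0.1) {
  coords <- ordination$coordinates
  if (!identical(rownames(coords), colnames(matrix))) {
    stop("ordination samples do not match the count matrix columns")
  }
  m <- unclass(matrix)
  sds <- apply(coords, 2, sd)
  ratio <- if (length(sds)) sds / sds[1] else numeric(0)
  L <- matrix(0, nrow(m), ncol(coords),
              dimnames = list(rownames(m), colnames(coords)))
  for (k in seq_len(ncol(coords))) {
    for (f in seq_len(nrow(m))) {
      x <- m[f, ]
      L[f, k] <- if (sd(x) == 0 || sds[k] == 0) 0
                 else cor(x, coords[, k]) * ratio[k]
    }
  }
  flagged <- rownames(L)[apply(abs(L), 1, max) > magnitude_cutoff]
  list(loadings = L, flagged = flagged)
}

# one-way PERMANOVA pseudo-F from a squared-distance matrix
permanova_F <- function(d2, groups) {
  N <- nrow(d2)
  a <- length(unique(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  list(F = (ss_among / (a - 1)) / (ss_within / (N - a)),
       R2 = ss_among / ss_total)
}

#' Permutational multivariate analysis of variance (one-way)
#'
#' Pseudo-F per Anderson's partitioning of a distance matrix:
#' \eqn{SS_T = \sum_{i<j} d_{ij}^2 / N}, \eqn{SS_W = \sum_g \sum_{i<j \in g}
#' d_{ij}^2 / n_g}, \eqn{F = ((SS_T - SS_W)/(a-1)) / (SS_W/(N-a))}. The
#' p-value is \eqn{(1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})}
#' under free whole-label permutation (no strata).
#'
#' @param dist symmetric dissimilarity matrix.
#' @param groups group label per sample (>= 2 groups, each with >= 2
#'   samples).
#' @param n_perm number of label permutations (default 999).
#' @param seed seed for the permutation stream, recorded in the result.
#' @return list with `pseudo_F`, `R2`, `p_value`, `n_permutations`, `seed`.
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = 1) {
  dist <- as.matrix(dist)
  groups <- as.character(groups)
  if (length(groups) != nrow(dist)) stop("one group label per sample required")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("PERMANOVA needs at least 2 groups")
  if (any(sizes < 2)) {
    stop("group of size 1: ", names(sizes)[which(sizes < 2)[1]])
  }
  d2 <- dist^2
  obs <- permanova_F(d2, groups)
  with_rng(substream_seed(seed, "permutation"), {
    ge <- 0L
    for (b in seq_len(n_perm)) {
      fp <- permanova_F(d2, sample(groups))$F
      if (fp >= obs$F) ge <- ge + 1L
    }
    list(pseudo_F = obs$F, R2 = obs$R2,
         p_value = (1 + ge) / (1 + n_perm),
         n_permutations = n_perm, seed = seed)
  })
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Fits a one-way ANOVA; when (and only when) the overall test is
#' significant at `alpha`, pairwise Tukey honest-significant-difference
#' p-values define a compact letter display in which groups sharing a
#' letter are not significantly different. Both the ANOVA table and the
#' Tukey comparisons are always returned.
#'
#' @param values numeric observations.
#' @param groups group label per observation (>= 2 groups of >= 2).
#' @param alpha significance level (default 0.05).
#' @return list with `F`, `p_value`, `tukey` (data.frame of pairwise
#'   adjusted p), `letters` (named per group), `significant`.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2)) {
    stop("need >= 2 groups with >= 2 observations each")
  }
  within_var <- tapply(values, groups, var)
  if (all(within_var == 0)) {
    stop("zero within-group variance in every group; F is undefined")
  }
  fit <- aov(values ~ groups)
  tab <- summary(fit)[[1]]
  Fval <- tab["groups", "F value"]
  p <- tab["groups", "Pr(>F)"]
  tk <- TukeyHSD(fit)$groups
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  sig <- p < alpha
  letters_out <- if (sig) {
    cld_letters(levels(groups), tukey$comparison, tukey$p_adj < alpha)
  } else {
    setNames(rep("a", nlevels(groups)), levels(groups))
  }
  list(F = Fval, p_value = p, tukey = tukey, letters = letters_out,
       significant = sig)
}

# compact letter display by insert-and-absorb over significant pairs
cld_letters <- function(levels, comparisons, significant) {
  sets <- list(levels)
  pairs <- strsplit(comparisons, "-", fixed = TRUE)
  for (k in which(significant)) {
    a <- pairs[[k]][1]; b <- pairs[[k]][2]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) {
      for (j in seq_along(new_sets)) {
        if (i != j && keep[j] &&
            all(new_sets[[i]] %in% new_sets[[j]]) &&
            !(all(new_sets[[j]] %in% new_sets[[i]]) && i < j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    sets <- unique(new_sets[keep])
  }
  out <- setNames(rep("", length(levels)), levels)
  for (i in seq_along(sets)) {
    for (g in sets[[i]]) out[g] <- paste0(out[g], letters[i])
  }
  out
}
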