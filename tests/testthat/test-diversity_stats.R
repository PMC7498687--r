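test_that("Chao1 matches hand-computed values and stays above observed richness", {
  r <- chao1(c(5, 5, 5))
  expect_equal(r$chao1, 3)          # no singletons or doubletons
  expect_equal(r$observed_S, 3)

  r2 <- chao1(c(1, 1, 2, 2, 3))     # f1 = 2, f2 = 2
  expect_equal(r2$chao1, 5 + 2 * 1 / (2 * 3))
  expect_equal(chao1(c(1, 1, 2, 2, 3), bias_corrected = FALSE)$chao1,
               5 + 4 / 4)

  expect_error(chao1(c(1.5, 2)), "integer")

  withr::local_seed(5)
  for (i in 1:1000) {
    x <- rpois(sample(5:40, 1), sample(1:5, 1))
    r <- chao1(x)
    expect_gte(r$chao1, r$observed_S)
    expect_gte(r$chao1_se, 0)
    if (r$f1 == 0) expect_equal(r$chao1, r$observed_S)
  }
})

test_that("rarefaction closed form hits its endpoints and the MC oracle", {
  x <- c(5, 3, 2, 1, 0)
  rc <- rarefaction_curve(x, c(1, sum(x)))
  expect_equal(rc$expected_richness[1], 1)
  expect_equal(rc$expected_richness[2], 4)  # full depth = observed richness
  expect_error(rarefaction_curve(x, 12), "exceeds")

  withr::local_seed(9)
  x <- rpois(25, 4); x <- x[x > 0]
  n <- floor(sum(x) / 2)
  closed <- rarefaction_curve(x, n)$expected_richness
  pool <- rep(seq_along(x), x)
  draws <- replicate(1000, length(unique(sample(pool, n))))
  expect_lt(abs(closed - mean(draws)), 3 * sd(draws) / sqrt(1000) + 1e-9)
})

test_that("normalization scales columns exactly and rarefying is reproducible", {
  m <- count_matrix(matrix(c(10L, 30L, 60L, 5L, 10L, 85L), 3, 2,
                           dimnames = list(c("a", "b", "c"), c("s1", "s2"))),
                    "ASV")
  norm <- normalize_counts(m, target = 100000)
  expect_equal(unclass(norm)[, "s1"], c(a = 10000, b = 30000, c = 60000))
  expect_true(all(abs(colSums(norm) - 100000) < 1e-9))
  expect_true(is_normalized(norm))

  big <- count_matrix(matrix(rpois(40, 50), 10, 4,
                             dimnames = list(sprintf("f%d", 1:10),
                                             sprintf("s%d", 1:4))), "ASV")
  r1 <- normalize_counts(big, target = 100, method = "rarefy", seed = 3)
  r2 <- normalize_counts(big, target = 100, method = "rarefy", seed = 3)
  expect_identical(unclass(r1), unclass(r2))
  expect_true(all(colSums(r1) == 100))
  expect_true(all(unclass(r1) <= unclass(big)))

  shallow <- count_matrix(matrix(c(5L, 2L, 100L, 80L), 2, 2,
                                 dimnames = list(c("a", "b"), c("lo", "hi"))),
                          "ASV")
  expect_warning(rr <- normalize_counts(shallow, 50, method = "rarefy"),
                 "dropping samples.*lo")
  expect_equal(colnames(rr), "hi")

  zero <- count_matrix(matrix(c(0L, 0L, 1L, 2L), 2, 2,
                              dimnames = list(c("a", "b"), c("z", "s"))),
                       "ASV")
  expect_error(normalize_counts(zero), "zero total.*z")
})

test_that("Bray-Curtis matches hand values, bounds and joint-rescaling invariance", {
  m <- count_matrix(matrix(c(6, 0, 2, 2, 2, 0), 3, 2,
                           dimnames = list(c("a", "b", "c"), c("x", "y"))),
                    "ASV")
  d <- bray_curtis(m)
  expect_equal(d["x", "y"], 1 - 2 * 2 / 12)
  expect_equal(diag(d), c(x = 0, y = 0))

  same <- count_matrix(matrix(c(3L, 1L, 3L, 1L), 2, 2,
                              dimnames = list(c("a", "b"), c("x", "y"))), "ASV")
  expect_equal(bray_curtis(same)["x", "y"], 0)
  disj <- count_matrix(matrix(c(3L, 0L, 0L, 4L), 2, 2,
                              dimnames = list(c("a", "b"), c("x", "y"))), "ASV")
  expect_equal(bray_curtis(disj)["x", "y"], 1)

  withr::local_seed(13)
  mm <- matrix(rpois(30, 10) + 0, 6, 5,
               dimnames = list(sprintf("f%d", 1:6), sprintf("s%d", 1:5)))
  cm <- count_matrix(mm, "ASV")
  d1 <- bray_curtis(cm)
  d2 <- bray_curtis(count_matrix(mm * 7, "ASV", normalized = TRUE))
  expect_equal(d1, d2)  # invariant to joint rescaling
  expect_true(all(d1 >= 0 & d1 <= 1))
  expect_equal(d1, t(d1))
})

test_that("PCoA reconstructs Euclidean configurations and reports eigenvalues", {
  withr::local_seed(19)
  pts <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("s", 1:5), NULL))
  d <- as.matrix(dist(pts))
  ord <- pcoa(d)
  expect_equal(ncol(ord$coordinates), 2)  # planar data: 2 positive eigenvalues
  expect_lt(max(abs(as.matrix(dist(ord$coordinates)) - d)), 1e-8)
  expect_equal(ord$eigenvalues, sort(ord$eigenvalues, decreasing = TRUE))

  # eigenvalue sum equals the trace of the centered matrix
  A <- -0.5 * d^2
  J <- diag(5) - matrix(1 / 5, 5, 5)
  expect_equal(sum(ord$eigenvalues), sum(diag(J %*% A %*% J)))

  zero <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  ord0 <- pcoa(zero)
  expect_equal(ncol(ord0$coordinates), 0)
  expect_true(all(abs(ord0$eigenvalues) < 1e-12))

  # agreement with classical MDS (independent implementation)
  cmd <- cmdscale(d, k = 2, eig = TRUE)
  expect_equal(abs(ord$coordinates), abs(cmd$points), ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("biplot loadings behave under perfect correlation, constancy and sign flips", {
  withr::local_seed(29)
  pts <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), NULL))
  d <- as.matrix(dist(pts))
  ord <- pcoa(d)
  m <- rbind(axis_copy = ord$coordinates[, 1] - min(ord$coordinates[, 1]),
             flat = rep(5, 6),
             noise = rpois(6, 20))
  colnames(m) <- rownames(d)
  cm <- count_matrix(m, "ASV", normalized = TRUE)
  bl <- biplot_loadings(cm, ord)
  expect_equal(abs(bl$loadings["axis_copy", 1]), 1, tolerance = 1e-8)
  expect_lt(abs(bl$loadings["axis_copy", 2]),
            abs(bl$loadings["axis_copy", 1]))
  expect_equal(unname(bl$loadings["flat", ]), c(0, 0))
  expect_true("axis_copy" %in% bl$flagged)

  flipped <- ord
  flipped$coordinates[, 2] <- -flipped$coordinates[, 2]
  bl2 <- biplot_loadings(cm, flipped)
  expect_equal(bl2$loadings[, 2], -bl$loadings[, 2])
})

test_that("PERMANOVA pseudo-F matches vegan and exhaustive permutation logic", {
  withr::local_seed(37)
  for (i in 1:20) {
    d <- rand_dist(n = 8)
    g <- rep(c("a", "b"), each = 4)
    ours <- permanova(d, g, n_perm = 99, seed = i)
    ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 2)
    expect_equal(ours$pseudo_F, ref$F[1], tolerance = 1e-10)
    expect_equal(ours$R2, ref$R2[1], tolerance = 1e-10)
  }

  # complete separation attains (near-)minimum p; a sampled permutation can
  # reproduce the original partition by chance, so allow one such duplicate
  far <- rand_dist(n = 16, sep = 60)
  g <- rep(c("a", "b"), each = 8)
  sep <- permanova(far, g, n_perm = 199, seed = 1)
  expect_lte(sep$p_value, 2 / 200)

  # sampled p agrees with exhaustive enumeration at N = 6
  d6 <- rand_dist(n = 6)
  g6 <- rep(c("a", "b"), each = 3)
  obs <- obulink:::permanova_F(d6^2, g6)$F
  perms <- all_perms(g6)
  fs <- vapply(perms, function(p) obulink:::permanova_F(d6^2, p)$F, numeric(1))
  exact_p <- mean(fs >= obs - 1e-12)
  ours6 <- permanova(d6, g6, n_perm = 999, seed = 4)
  expect_lt(abs(ours6$p_value - exact_p),
            3 * sqrt(exact_p * (1 - exact_p) / 999) + 2e-3)

  expect_error(permanova(d6, c("a", "a", "a", "a", "a", "b")), "size 1")
})

test_that("PERMANOVA p-values are uniform under an exchangeable null", {
  withr::local_seed(43)
  ps <- replicate(150, {
    d <- rand_dist(n = 8)
    permanova(d, sample(rep(c("a", "b"), each = 4)), n_perm = 99,
              seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.001)
})

test_that("ANOVA with Tukey letters matches classical identities", {
  # identical group means: no significance, one shared letter
  same <- anova_tukey(c(1, 2, 3, 1, 2, 3), rep(c("g1", "g2"), each = 3))
  expect_false(same$significant)
  expect_equal(unname(same$letters), c("a", "a"))

  # two groups: F equals the pooled-variance t squared
  v <- c(4.1, 5.2, 4.7, 8.9, 9.4, 8.2)
  g <- rep(c("lo", "hi"), each = 3)
  at <- anova_tukey(v, g)
  tt <- t.test(v ~ factor(g, levels = c("lo", "hi")), var.equal = TRUE)
  expect_equal(at$F, unname(tt$statistic)^2, tolerance = 1e-10)

  # Tukey p matches a direct studentized-range computation
  v3 <- c(1.2, 1.9, 1.4, 5.5, 6.1, 5.8, 9.9, 10.4, 10.1)
  g3 <- rep(c("A", "B", "C"), each = 3)
  at3 <- anova_tukey(v3, g3)
  fit <- aov(v3 ~ factor(g3))
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  qstat <- abs(mean(v3[4:6]) - mean(v3[1:3])) / sqrt(mse / 3)
  p_ref <- ptukey(qstat, nmeans = 3, df = 6, lower.tail = FALSE)
  expect_equal(at3$tukey$p_adj[at3$tukey$comparison == "B-A"], p_ref,
               tolerance = 1e-6)
  expect_length(unique(at3$letters), 3)  # all groups differ

  expect_error(anova_tukey(c(1, 1, 2, 2), rep(c("a", "b"), each = 2)),
               "zero within-group variance")
})
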