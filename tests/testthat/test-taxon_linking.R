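make_cm <- function(m, kind = "ASV") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("f%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  count_matrix(m, kind)
}

test_that("cleaning applies the prevalence-and-total rule in both readings", {
  sp <- make_cm(rbind(one_low = c(5L, 0L, 0L),     # 1 sample, total 5
                      one_high = c(50L, 0L, 0L),   # 1 sample, total 50
                      multi_low = c(1L, 2L, 1L),   # 3 samples, total 4
                      keep = c(10L, 10L, 10L)))
  ob <- make_cm(rbind(o1 = c(3L, 4L, 5L)), kind = "OBU_KS")

  and_res <- clean_matrices(sp, ob, min_total = 10, combine = "AND")
  expect_setequal(rownames(and_res$species), c("one_high", "multi_low", "keep"))
  expect_equal(and_res$report$feature_id, "one_low")
  expect_equal(and_res$report$rule, "sparse+low")

  or_res <- clean_matrices(sp, ob, min_total = 10, combine = "OR")
  expect_setequal(rownames(or_res$species), "keep")

  one_col <- make_cm(matrix(1L, 2, 1))
  expect_error(clean_matrices(one_col, one_col), "fewer than 2 shared samples")
})

test_that("collinear species are merged to their highest-count representative", {
  x <- c(3L, 6L, 9L, 12L)
  sp <- make_cm(rbind(dup_a = x, dup_b = x, triple = 3L * x,
                      flat = c(4L, 4L, 4L, 4L),
                      indep = c(9L, 2L, 7L, 4L)))
  res <- dedup_collinear_species(sp)
  # dup_a, dup_b and triple are mutually r2 = 1; triple has the largest total
  expect_setequal(rownames(res$species), c("triple", "indep"))
  expect_setequal(res$report$species_id[res$report$reason == "collinear"],
                  c("dup_a", "dup_b"))
  expect_equal(res$report$representative[res$report$species_id == "dup_a"],
               "triple")
  expect_equal(res$report$reason[res$report$species_id == "flat"], "constant")

  withr::local_seed(31)
  indep3 <- make_cm(matrix(rpois(30, 20), 3, 10))
  res3 <- dedup_collinear_species(indep3)
  expect_equal(nrow(res3$species), 3)  # independent species all kept
})

test_that("no-intercept fit matches closed forms, lm, and is scale-equivariant", {
  # exact fit: residuals vanish, p at the underflow-safe minimum
  exact <- fit_link(c(2, 4, 6), c(1, 2, 3))
  expect_equal(exact$alpha_hat, 2)
  expect_equal(exact$p_value, .Machine$double.xmin)
  expect_equal(exact$r2, 1)

  # hand-evaluated closed forms
  h <- fit_link(c(3, 1, 2), c(1, 2, 3))
  expect_equal(h$alpha_hat, 11 / 14)

  withr::local_seed(41)
  for (i in 1:100) {
    n <- sample(3:15, 1)
    x <- rlnorm(n); y <- rnorm(n, 2 * x, 1)
    ours <- fit_link(y, x)
    ref <- summary(lm(y ~ x + 0))$coefficients
    expect_equal(ours$alpha_hat, ref[1, "Estimate"], tolerance = 1e-10)
    expect_equal(ours$t_stat, ref[1, "t value"], tolerance = 1e-10)
    expect_equal(ours$p_value, ref[1, "Pr(>|t|)"], tolerance = 1e-10)
  }

  # scaling y by c scales alpha by c and leaves t and p unchanged
  x <- c(1, 3, 2, 5); y <- c(2.2, 5.4, 4.6, 9.1)
  a <- fit_link(y, x); b <- fit_link(10 * y, x)
  expect_equal(b$alpha_hat, 10 * a$alpha_hat)
  expect_equal(b$t_stat, a$t_stat)
  expect_equal(b$p_value, a$p_value)

  expect_error(fit_link(c(1, 2), c(0, 0)), "all-zero species")
  expect_error(fit_link(1, 1), "at least 2")
})

test_that("screening recovers planted links and reports the test count", {
  cfg <- generator_config(n_samples = 20, n_species = 30, n_producers = 5,
                          obus_per_producer = 2, n_background_obus = 5,
                          count_depth = 50000, nb_dispersion = 0.1,
                          low_abundance_fraction = 0, seed = 47)
  com <- generate_community(cfg)
  obu <- generate_obu_counts(com$species, com$truth, cfg)
  links <- screen_links(com$species, obu, p_threshold = 0.001)
  expect_equal(attr(links, "n_tests"), 30 * 15)
  truth_keys <- with(com$truth$planted_links, paste(obu_id, species_id))
  hit_keys <- paste(links$obu_id, links$species_id)
  expect_gte(mean(truth_keys %in% hit_keys), 0.9)
  expect_false(is.unsorted(links$obu_id))

  empty <- screen_links(com$species,
                        make_cm(matrix(0L, 0, 20,
                                       dimnames = list(NULL,
                                                       colnames(com$species))),
                                kind = "OBU_KS"))
  expect_equal(nrow(empty), 0)
})

test_that("screen retention matches the threshold under the model null", {
  withr::local_seed(53)
  n <- 10; n_sp <- 30; n_ob <- 200
  x <- matrix(rlnorm(n_sp * n, 2, 1), n_sp, n,
              dimnames = list(sprintf("SP%03d", 1:n_sp), sprintf("s%d", 1:n)))
  y <- matrix(rnorm(n_ob * n), n_ob, n,
              dimnames = list(sprintf("OB%03d", 1:n_ob), sprintf("s%d", 1:n)))
  # plain matrices: mean-zero y is the model's null and cannot be a
  # count matrix
  links <- screen_links(x, y, p_threshold = 0.05)
  frac <- nrow(links) / attr(links, "n_tests")
  se <- sqrt(0.05 * 0.95 / attr(links, "n_tests"))
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("genus summaries use union semantics and keep linkless genera", {
  tax <- data.frame(feature_id = c("sp1", "sp2", "sp3"),
                    domain = "Bacteria", phylum = "P", class = "C",
                    order = c("O1", "O1", "O2"), family = "F",
                    genus = c("GenA", "GenA", "GenB"),
                    species = c("a1", "a2", "b1"), stringsAsFactors = FALSE)
  spm <- make_cm(matrix(c(10L, 40L, 50L, 20L, 30L, 50L), 3, 2,
                        dimnames = list(c("sp1", "sp2", "sp3"),
                                        c("s1", "s2"))))
  links <- data.frame(obu_id = c("OBU_1", "OBU_1"),
                      species_id = c("sp1", "sp2"),
                      stringsAsFactors = FALSE)
  gs <- summarize_by_genus(links, tax, spm)
  expect_equal(gs$n_linked_obus[gs$genus == "GenA"], 1)  # union, not sum
  expect_equal(gs$n_linked_obus[gs$genus == "GenB"], 0)  # linkless included
  expect_equal(sum(gs$mean_rel_abundance), 1)

  bad <- data.frame(obu_id = "OBU_9", species_id = "spX")
  expect_error(summarize_by_genus(bad, tax, spm), "missing from taxonomy.*spX")
})

test_that("per-genus OBU tallies match a direct tabulation on synthetic data", {
  cfg <- generator_config(n_samples = 10, n_species = 30, n_producers = 6,
                          obus_per_producer = 3, n_background_obus = 5,
                          count_depth = 50000, nb_dispersion = 0.05,
                          low_abundance_fraction = 0, seed = 59)
  com <- generate_community(cfg)
  obu <- generate_obu_counts(com$species, com$truth, cfg)
  tax <- generate_taxonomy(rownames(com$species), n_genera = 10, n_orders = 3)
  links <- screen_links(com$species, obu, p_threshold = 0.001)
  gs <- summarize_by_genus(links, tax, com$species)

  direct <- vapply(unique(tax$genus), function(g) {
    members <- tax$feature_id[tax$genus == g]
    length(unique(links$obu_id[links$species_id %in% members]))
  }, integer(1))
  expect_equal(median(gs$n_linked_obus), median(direct))
  expect_equal(range(gs$n_linked_obus), range(direct))
  expect_equal(gs$n_linked_obus[match(names(direct), gs$genus)],
               unname(direct))
})

test_that("abundance-vs-potential regression behaves at its extremes", {
  s <- data.frame(genus = letters[1:5], order = "O",
                  mean_rel_abundance = c(0.1, 0.2, 0.3, 0.25, 0.15),
                  n_linked_obus = c(2, 4, 6, 5, 3))
  # counts exactly linear in abundance (summary.lm warns on perfect fits)
  exact <- suppressWarnings(abundance_vs_potential(s))
  expect_equal(exact$r2, 1)

  expect_error(abundance_vs_potential(s[1:2, ]), "at least 3")
  s0 <- s; s0$mean_rel_abundance <- 0.2
  expect_error(abundance_vs_potential(s0), "zero variance")
})
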