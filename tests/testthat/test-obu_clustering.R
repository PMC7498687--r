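test_that("trimming truncates to target lengths and discards short pairs", {
  pairs <- data.frame(
    read_id = c("a", "b", "c"), sample_id = "s1",
    forward = c(strrep("A", 300), strrep("C", 240), strrep("G", 100)),
    reverse = c(strrep("T", 300), strrep("G", 175), strrep("A", 200)),
    stringsAsFactors = FALSE)
  tr <- trim_pairs(pairs)
  expect_equal(tr$n_discarded, 1)
  expect_equal(nchar(tr$pairs$forward), c(240, 240))
  expect_equal(nchar(tr$pairs$reverse), c(175, 175))
  expect_equal(tr$pairs$forward[1], strrep("A", 240))
  expect_equal(tr$pairs$forward[2], strrep("C", 240))  # boundary: unchanged
  expect_error(trim_pairs(pairs[c(1, 1), ]), "duplicated read ids")
})

test_that("joining inserts a single N spacer before the reverse complement", {
  expect_equal(join_pairs("ACGT", "AACC"), "ACGTNGGTT")
  fwd <- strrep("A", 240); rev <- strrep("C", 175)
  joined <- join_pairs(fwd, rev)
  expect_equal(nchar(joined), 240 + 1 + 175)
  expect_equal(sum(strsplit(joined, "")[[1]] == "N"), 1)
  expect_error(join_pairs("ACGT", ""), "empty")
})

test_that("reverse complement maps standard bases and preserves N", {
  expect_equal(reverse_complement("AACC"), "GGTT")
  expect_equal(reverse_complement("ACGTN"), "NACGT")
  expect_equal(reverse_complement(c("A", "CG")), c("T", "CG"))
})

test_that("alignment identity matches the pure-R reference on random pairs", {
  withr::local_seed(17)
  for (i in 1:100) {
    len <- sample(30:70, 1)
    a <- rand_dna(len)
    b <- switch(sample(3, 1),
                mutate_dna(a, sample(1:8, 1)),   # near-identical
                rand_dna(sample(30:70, 1)),      # unrelated
                sub("^(.{10})", "\\1N", mutate_dna(a, 2)))  # with an N
    expect_equal(seq_identity(a, b), ref_nw_identity(a, b), tolerance = 1e-12)
  }
  expect_equal(seq_identity("ACGT", "ACGT"), 1)
  expect_equal(seq_identity("AAAA", "AATT"), 0.5)
  expect_equal(seq_identity("ACGTN", "ACGTA"), 1)  # N column excluded
})

test_that("greedy clustering separates dissimilar and merges identical reads", {
  cl <- cluster_greedy(c("ACGTACGTAC", "ACGTACGTAC"), threshold = 0.97)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$total_weight, 2)

  a <- strrep("ACGT", 10)
  b <- strrep("TTGA", 10)  # far below 95%
  cl2 <- cluster_greedy(c(a, b), threshold = 0.95)
  expect_length(cl2, 2)

  expect_error(cluster_greedy("ACGT", threshold = 1.5), "\\(0, 1\\]")
  expect_length(cluster_greedy(character(0), threshold = 0.95), 0)
})

test_that("greedy clustering recovers planted structure and matches the all-pairs reference", {
  withr::local_seed(23)
  n_obu <- 5
  centroids <- replicate(n_obu, rand_dna(150))
  reads <- character(0); truth <- character(0)
  for (k in seq_len(n_obu)) {
    for (r in 1:20) {
      reads <- c(reads, mutate_dna(centroids[k], sample(0:2, 1)))
      truth <- c(truth, sprintf("obu%d", k))
    }
  }
  ids <- sprintf("r%03d", seq_along(reads))
  cl <- cluster_greedy(reads, ids = ids, threshold = 0.95)
  expect_length(cl, n_obu)
  got <- partition_of(cl)
  want <- unname(split(ids, truth))
  expect_true(same_partition(got, lapply(want, sort)))

  ref <- ref_cluster_allpairs(reads, ids = ids, threshold = 0.95)
  expect_true(same_partition(got, lapply(ref, sort)))

  # input order invariance (the sort is total)
  perm <- sample(seq_along(reads))
  cl_shuf <- cluster_greedy(reads[perm], ids = ids[perm], threshold = 0.95)
  expect_true(same_partition(partition_of(cl_shuf), got))

  # the k-mer prefilter never changes the result
  cl_pf <- cluster_greedy(reads, ids = ids, threshold = 0.95,
                          prefilter = TRUE)
  expect_identical(cl_pf, cl)
})

test_that("two-round pipeline builds the OBU table and discards singletons", {
  one <- data.frame(read_id = sprintf("r%d", 1:4), sample_id = "s1",
                    forward = strrep("ACGT", 75), reverse = strrep("TGCA", 60),
                    stringsAsFactors = FALSE)
  res <- run_obu_pipeline(one, domain = "KS")
  expect_equal(nrow(res$counts), 1)
  expect_equal(sum(res$counts), 4)
  expect_equal(feature_kind(res$counts), "OBU_KS")

  # a single read total is a singleton and is discarded
  res1 <- run_obu_pipeline(one[1, ], domain = "KS")
  expect_equal(nrow(res1$counts), 0)
  expect_equal(res1$discards$singleton_reads, 1)

  expect_warning(empty <- run_obu_pipeline(one[0, ], domain = "AD"),
                 "no input read pairs")
  expect_equal(dim(empty$counts), c(0, 0))
})

test_that("pipeline recovers planted OBU-by-sample counts and conserves reads", {
  cfg <- generator_config(n_samples = 3, n_species = 12, n_producers = 4,
                          obus_per_producer = 1, n_background_obus = 0,
                          count_depth = 3000, nb_dispersion = 0,
                          alpha_range = c(2, 2), low_abundance_fraction = 0,
                          seed = 71)
  com <- generate_community(cfg)
  obu <- generate_obu_counts(com$species, com$truth, cfg)
  rd <- generate_domain_reads(com$truth, cfg, obu, max_reads_per_cell = 6)
  res <- run_obu_pipeline(rd$reads, domain = "KS")

  # count conservation: final table + discards = input pairs
  expect_equal(sum(res$counts) + res$discards$trimmed +
                 res$discards$singleton_reads, nrow(rd$reads))

  # recovered table equals the truth table up to OBU relabeling
  truth_tab <- table(rd$reads$true_obu, rd$reads$sample_id)
  expect_equal(nrow(res$counts), nrow(truth_tab))
  got <- unclass(res$counts)[, colnames(truth_tab), drop = FALSE]
  match_rows <- vapply(rownames(truth_tab), function(tid) {
    any(apply(got, 1, function(r) all(r == truth_tab[tid, ])))
  }, logical(1))
  expect_true(all(match_rows))

  # memberships equal planted truth
  for (cl in res$clusters) {
    expect_length(unique(rd$truth$cluster_truth[cl$member_read_ids]), 1)
  }
})
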