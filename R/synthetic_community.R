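#' Configuration for the synthetic community generator
#'
#' Describes a simulated amplicon survey in which a subset of species are
#' secondary-metabolite producers: each producer carries one or more
#' biosynthetic domains (future OBUs) on its chromosome, so domain counts
#' co-occur linearly with the producer's 16S counts. The generator emulates
#' the statistical structure the downstream analysis assumes -- log-normal
#' species abundance profiles shared across replicate samples, OBU counts
#' proportional to producer counts plus overdispersed noise, background
#' OBUs independent of every species, and (optionally) producers forced to
#' low relative abundance.
#'
#' @param n_samples number of replicate samples.
#' @param n_species number of species (ASVs).
#' @param n_producers number of producer species (`<= n_species`).
#' @param obus_per_producer planted OBUs per producer.
#' @param n_background_obus OBUs independent of all species.
#' @param alpha_range range of planted slopes (OBU counts per species count);
#'   the real-data slope distribution is unknown, so this default is a
#'   placeholder and recorded with the truth.
#' @param abundance_meanlog,abundance_sdlog log-normal law for baseline
#'   species relative abundances.
#' @param replicate_sdlog per-sample log-normal jitter of relative
#'   abundances (replicate noise; replicates share the same baseline).
#' @param count_depth reads per sample (multinomial total).
#' @param nb_dispersion negative-binomial dispersion phi for OBU counts
#'   (variance mu + phi*mu^2); `0` gives the deterministic noise-free limit
#'   `round(alpha * species)`.
#' @param background_mean mean count of a background OBU per sample.
#' @param low_abundance_fraction fraction of producers forced below the
#'   relative-abundance ceiling.
#' @param low_abundance_ceiling relative-abundance ceiling for those
#'   producers (default 0.001, i.e. below 0.1%).
#' @param fwd_read_len,rev_read_len raw read lengths emitted in sequence
#'   mode (defaults 300/300 so that 240/175 trimming is exercised).
#' @param mutation_rate per-base substitution rate of reads around their
#'   OBU centroid (default keeps within-OBU identity above 98%).
#' @param seed master seed; each logical component (community, OBU counts,
#'   reads) draws from its own substream so stages can be regenerated
#'   independently.
#'
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_samples = 6, n_species = 50, n_producers = 10,
                             obus_per_producer = 2, n_background_obus = 10,
                             alpha_range = c(1, 5),
                             abundance_meanlog = 0, abundance_sdlog = 1.5,
                             replicate_sdlog = 0.3,
                             count_depth = 100000,
                             nb_dispersion = 0.1,
                             background_mean = 50,
                             low_abundance_fraction = 0.5,
                             low_abundance_ceiling = 0.001,
                             fwd_read_len = 300, rev_read_len = 300,
                             mutation_rate = 0.005,
                             seed = 1) {
  cfg <- list(n_samples = n_samples, n_species = n_species,
              n_producers = n_producers, obus_per_producer = obus_per_producer,
              n_background_obus = n_background_obus, alpha_range = alpha_range,
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              replicate_sdlog = replicate_sdlog, count_depth = count_depth,
              nb_dispersion = nb_dispersion, background_mean = background_mean,
              low_abundance_fraction = low_abundance_fraction,
              low_abundance_ceiling = low_abundance_ceiling,
              fwd_read_len = fwd_read_len, rev_read_len = rev_read_len,
              mutation_rate = mutation_rate, seed = seed)
  if (n_producers > n_species) {
    stop("infeasible config: n_producers exceeds n_species")
  }
  if (n_samples < 1 || n_species < 1 || count_depth < 1) {
    stop("infeasible config: sample count, species count and depth must be positive")
  }
  if (low_abundance_ceiling <= 0 || low_abundance_ceiling >= 1) {
    stop("low_abundance_ceiling must lie in (0, 1)")
  }
  if (low_abundance_fraction < 0 || low_abundance_fraction > 1) {
    stop("low_abundance_fraction must lie in [0, 1]")
  }
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic species count matrix with known truth
#'
#' Baseline relative abundances are drawn from the configured log-normal
#' law and shared by all replicate samples up to log-normal jitter; each
#' sample is then a multinomial draw of `count_depth` reads. A configured
#' fraction of producers is rescaled below the low-abundance ceiling before
#' sampling, emulating rare taxa with rich biosynthetic potential. The
#' returned truth records producer identities and the planted
#' species-to-OBU links with their slopes.
#'
#' @param config a [generator_config()].
#' @return list with elements `species` (an ASV [count_matrix()]) and
#'   `truth` (planted links, producer ids, baseline abundances, config).
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_rng(substream_seed(config$seed, "community"), {
    ns <- config$n_species
    species_ids <- sprintf("SP_%04d", seq_len(ns))
    base <- rlnorm(ns, config$abundance_meanlog, config$abundance_sdlog)
    base <- base / sum(base)

    producer_ids <- character(0)
    low_ids <- character(0)
    if (config$n_producers > 0) {
      producer_ids <- sample(species_ids, config$n_producers)
      n_low <- round(config$low_abundance_fraction * config$n_producers)
      if (n_low > 0) {
        low_ids <- producer_ids[seq_len(n_low)]
        idx <- match(low_ids, species_ids)
        # pin each low producer at 20-80% of the ceiling, renormalize the rest
        target <- config$low_abundance_ceiling * runif(n_low, 0.2, 0.8)
        rest <- setdiff(seq_len(ns), idx)
        base[idx] <- target
        base[rest] <- base[rest] / sum(base[rest]) * (1 - sum(target))
      }
    }

    counts <- matrix(0L, ns, config$n_samples,
                     dimnames = list(species_ids,
                                     sprintf("S%02d", seq_len(config$n_samples))))
    for (s in seq_len(config$n_samples)) {
      p <- base * rlnorm(ns, 0, config$replicate_sdlog)
      counts[, s] <- rmultinom(1, config$count_depth, p)[, 1]
    }

    links <- data.frame(species_id = character(), obu_id = character(),
                        alpha = numeric(), stringsAsFactors = FALSE)
    if (config$n_producers > 0 && config$obus_per_producer > 0) {
      links <- data.frame(
        species_id = rep(producer_ids, each = config$obus_per_producer),
        obu_id = sprintf("OBU_%04d",
                         seq_len(config$n_producers * config$obus_per_producer)),
        alpha = runif(config$n_producers * config$obus_per_producer,
                      config$alpha_range[1], config$alpha_range[2]),
        stringsAsFactors = FALSE)
    }
    background_ids <- if (config$n_background_obus > 0) {
      sprintf("OBU_%04d", nrow(links) + seq_len(config$n_background_obus))
    } else character(0)

    truth <- structure(
      list(planted_links = links, producer_ids = producer_ids,
           low_abundance_ids = low_ids, background_obu_ids = background_ids,
           base_abundance = setNames(base, species_ids),
           cluster_truth = NULL, config = config),
      class = "synthetic_truth")
    list(species = count_matrix(counts, "ASV"), truth = truth)
  })
}

#' Generate OBU counts linearly coupled to their producer species
#'
#' For every planted link the OBU count in sample `s` is negative-binomial
#' with mean `alpha * species_count(s)`; background OBUs are drawn
#' independently of all species with a per-OBU log-normal baseline mean.
#' When dispersion is 0 the noise-free limit returns the exact conditional
#' means `alpha * x`, so the OBU/species ratio equals `alpha` in every
#' sample; these are fractional for non-integer `alpha`, in which case the
#' matrix is flagged as normalized (integer-only consumers such as Chao1
#' apply to noisy or integer-slope data).
#'
#' @param species_matrix species [count_matrix()] from [generate_community()].
#' @param truth the matching `synthetic_truth`.
#' @param config the matching [generator_config()].
#' @param feature_kind `"OBU_KS"` or `"OBU_AD"`.
#' @return an OBU [count_matrix()].
#' @export
generate_obu_counts <- function(species_matrix, truth, config,
                                feature_kind = "OBU_KS") {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_rng(substream_seed(config$seed, "obu"), {
    links <- truth$planted_links
    obu_ids <- c(links$obu_id, truth$background_obu_ids)
    m <- matrix(0, length(obu_ids), ncol(species_matrix),
                dimnames = list(obu_ids, colnames(species_matrix)))
    draw_nb <- function(mu) {
      if (config$nb_dispersion == 0) {
        mu  # exact noise-free limit
      } else {
        rnbinom(length(mu), size = 1 / config$nb_dispersion, mu = mu)
      }
    }
    for (k in seq_len(nrow(links))) {
      mu <- links$alpha[k] * unclass(species_matrix)[links$species_id[k], ]
      m[links$obu_id[k], ] <- draw_nb(mu)
    }
    for (b in truth$background_obu_ids) {
      # integer per-OBU baseline so the noise-free limit stays integral
      mu <- rep(max(1, round(config$background_mean * rlnorm(1, 0, 0.5))),
                ncol(species_matrix))
      m[b, ] <- draw_nb(mu)
    }
    integral <- all(abs(m - round(m)) < 1e-9)
    if (integral) storage.mode(m) <- "integer"
    count_matrix(m, feature_kind = feature_kind, normalized = !integral)
  })
}

#' Generate paired domain reads with known cluster structure
#'
#' Sequence mode of the generator: each OBU gets a random centroid sequence
#' (pairwise identity between centroids below 90% by construction, verified
#' and re-drawn if violated), and each read pair is the centroid's two ends
#' mutated at the configured per-base rate, so true cluster memberships are
#' known. Reads per (OBU, sample) cell follow the supplied OBU count
#' matrix.
#'
#' @param truth `synthetic_truth` (updated copy is returned).
#' @param config the matching [generator_config()].
#' @param obu_counts OBU [count_matrix()] giving reads per OBU and sample;
#'   cells may be capped with `max_reads_per_cell` to keep read sets small.
#' @param max_reads_per_cell cap on reads emitted per (OBU, sample).
#' @return list with `reads` (data.frame: `read_id`, `sample_id`, `forward`,
#'   `reverse`, `true_obu`) and `truth` with `cluster_truth` filled.
#' @export
generate_domain_reads <- function(truth, config, obu_counts,
                                  max_reads_per_cell = 25) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_rng(substream_seed(config$seed, "reads"), {
    obu_ids <- rownames(obu_counts)
    gene_len <- config$fwd_read_len + config$rev_read_len - 80  # overlapping ends
    if (gene_len < 50) stop("infeasible config: read lengths too short")
    centroids <- draw_divergent_sequences(length(obu_ids), gene_len,
                                          max_identity = 0.90)
    names(centroids) <- obu_ids

    rows <- list()
    for (ob in obu_ids) {
      for (s in colnames(obu_counts)) {
        n_reads <- min(unclass(obu_counts)[ob, s], max_reads_per_cell)
        if (n_reads < 1) next
        for (r in seq_len(n_reads)) {
          gene <- mutate_sequence(centroids[[ob]], config$mutation_rate)
          rows[[length(rows) + 1L]] <- data.frame(
            read_id = sprintf("%s_%s_r%03d", s, ob, r),
            sample_id = s,
            forward = substr(gene, 1, config$fwd_read_len),
            reverse = reverse_complement(
              substr(gene, nchar(gene) - config$rev_read_len + 1L,
                     nchar(gene))),
            true_obu = ob, stringsAsFactors = FALSE)
        }
      }
    }
    reads <- if (length(rows)) do.call(rbind, rows) else
      data.frame(read_id = character(), sample_id = character(),
                 forward = character(), reverse = character(),
                 true_obu = character(), stringsAsFactors = FALSE)
    truth$cluster_truth <- setNames(reads$true_obu, reads$read_id)
    truth$centroids <- centroids
    list(reads = reads, truth = truth)
  })
}

# random DNA sequences with all pairwise identities below max_identity;
# random sequences of this length essentially never collide, but we verify
# and re-draw offenders rather than assume it
draw_divergent_sequences <- function(n, len, max_identity = 0.90,
                                     max_tries = 50) {
  out <- character(0)
  tries <- 0
  while (length(out) < n) {
    cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
    ok <- all(vapply(out, function(s) seq_identity(cand, s) < max_identity,
                     logical(1)))
    if (ok) out <- c(out, cand) else tries <- tries + 1
    if (tries > max_tries) {
      stop("infeasible config: cannot draw ", n,
           " centroids below ", max_identity, " identity at length ", len)
    }
  }
  out
}

mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    for (i in hit) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    }
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic taxonomy for the simulated species
#'
#' Assigns species to a configurable number of genera and orders (round
#' robin, so congeneric species exist), producing a 7-rank taxonomy whose
#' genus level is the aggregation target of the linking stage.
#'
#' @param species_ids character vector of species ids.
#' @param n_genera,n_orders number of distinct genera and orders.
#' @param seed seed for the (deterministic) assignment.
#' @return taxonomy data.frame (see [read_taxonomy()]).
#' @export
generate_taxonomy <- function(species_ids, n_genera = 20, n_orders = 5,
                              seed = 1) {
  with_rng(substream_seed(seed, "taxonomy"), {
    n <- length(species_ids)
    genus <- sprintf("Genus_%03d", rep_len(seq_len(n_genera), n))
    g2o <- rep_len(seq_len(n_orders), n_genera)  # each genus in one order
    ord <- sprintf("Order_%02d", g2o[rep_len(seq_len(n_genera), n)])
    data.frame(feature_id = species_ids, domain = "Bacteria",
               phylum = "Phylum_01", class = "Class_01", order = ord,
               family = paste0("Family_", sub("Genus_", "", genus)),
               genus = genus,
               species = paste0(genus, "_sp", seq_len(n)),
               stringsAsFactors = FALSE)
  })
}
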