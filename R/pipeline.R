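#' Pipeline run configuration
#'
#' Collects every stage parameter with its standard default: 240/175 bp
#' trimming, 97% within-sample and 95% pooled clustering identity,
#' normalization to 100,000 reads, p < 0.001 link screen, 999 PERMANOVA
#' permutations. Round-trips losslessly through [write_run_config()] /
#' [read_run_config()].
#'
#' @param stages stages to execute, in dependency order.
#' @param fwd_len,rev_len trim targets (bp).
#' @param id1,id2 clustering identity thresholds.
#' @param norm_target normalization depth.
#' @param p_threshold link-screen p cutoff.
#' @param n_perm PERMANOVA permutations.
#' @param min_total cleaning total-read threshold.
#' @param link_scale `"normalized"` (default; per-`norm_target` abundances
#'   enter the link screen) or `"raw"` (raw counts; slopes change units,
#'   t and p are unchanged for equal-depth samples).
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(stages = c("cluster", "diversity", "link", "recover"),
                       fwd_len = 240, rev_len = 175, id1 = 0.97, id2 = 0.95,
                       norm_target = 100000, p_threshold = 0.001,
                       n_perm = 999, min_total = 10,
                       link_scale = c("normalized", "raw"), seed = 1) {
  link_scale <- match.arg(link_scale)
  structure(list(stages = stages, fwd_len = fwd_len, rev_len = rev_len,
                 id1 = id1, id2 = id2, norm_target = norm_target,
                 p_threshold = p_threshold, n_perm = n_perm,
                 min_total = min_total, link_scale = link_scale, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path file path for the flat key=value serialization.
#' @export
write_run_config <- function(config, path) {
  vals <- vapply(config, function(v) paste(v, collapse = ","), character(1))
  writeLines(paste0(names(config), "=", vals), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- run_config()
  for (p in kv) {
    key <- p[1]
    if (!key %in% names(out)) stop("unknown config key: ", key)
    raw <- strsplit(p[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(raw))
    out[[key]] <- if (anyNA(num)) raw else num
  }
  class(out) <- "run_config"
  out
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order -- clustering (when read
#' pairs are supplied), diversity statistics, per-niche link screening,
#' and cultured-fraction recovery -- writing TSV outputs and a JSON
#' provenance manifest into `out_dir`. A stage failure aborts the run with
#' the stage name. All TSV outputs are deterministic given the inputs and
#' the config seed.
#'
#' @param inputs list with (any of) `read_pairs` (named list per domain of
#'   read-pair data.frames), `species` ([count_matrix()]), `obu_tables`
#'   (named list of OBU [count_matrix()] objects; used when no read pairs
#'   are given), `taxonomy`, `metadata`, `pdna_tables` (named list, for
#'   the recovery stage).
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_all <- function(inputs, config = run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("obulink")),
                   r_version = as.character(getRversion()),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   seed = config$seed,
                   parameters = unclass(config)[setdiff(names(config), "stages")],
                   stages = list())
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  obu_tables <- inputs$obu_tables

  if ("cluster" %in% config$stages && !is.null(inputs$read_pairs)) {
    run_stage("cluster", function() {
      clustered <- list()
      for (dm in names(inputs$read_pairs)) {
        res <- run_obu_pipeline(inputs$read_pairs[[dm]], domain = dm,
                                fwd_len = config$fwd_len,
                                rev_len = config$rev_len,
                                id1 = config$id1, id2 = config$id2)
        write_count_table(res$counts,
                          file.path(out_dir, sprintf("obu_table_%s.tsv", dm)),
                          id_column = "obu_id")
        if (length(res$clusters)) {
          write_fasta(res$clusters,
                      file.path(out_dir, sprintf("obu_centroids_%s.fasta", dm)))
        }
        clustered[[dm]] <- res
      }
      manifest$stages$cluster <<- lapply(clustered, function(r) {
        list(n_obus = nrow(r$counts), n_reads_kept = sum(r$counts),
             discards = r$discards)
      })
      # read-derived tables only replace the inputs when none were given
      if (is.null(obu_tables)) {
        obu_tables <<- lapply(clustered, `[[`, "counts")
      }
    })
  }

  if ("diversity" %in% config$stages) {
    run_stage("diversity", function() {
      tabs <- c(list(species = inputs$species), obu_tables)
      tabs <- tabs[!vapply(tabs, is.null, logical(1))]
      rich <- do.call(rbind, lapply(names(tabs), function(nm) {
        cbind(table = nm, chao1_table(tabs[[nm]]))
      }))
      write.table(rich, file.path(out_dir, "richness.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      stats_rows <- list()
      for (nm in names(tabs)) {
        norm <- normalize_counts(tabs[[nm]], target = config$norm_target)
        d <- bray_curtis(norm)
        write.table(data.frame(sample_id = rownames(d), d,
                               check.names = FALSE),
                    file.path(out_dir, sprintf("braycurtis_%s.tsv", nm)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        ord <- pcoa(d)
        write.table(data.frame(sample_id = rownames(ord$coordinates),
                               ord$coordinates, check.names = FALSE),
                    file.path(out_dir, sprintf("pcoa_%s.tsv", nm)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(inputs$metadata)) {
          md <- inputs$metadata
          grp <- md$source[match(colnames(norm), md$sample_id)]
          if (length(unique(grp)) >= 2 && all(table(grp) >= 2)) {
            pm <- permanova(d, grp, n_perm = config$n_perm,
                            seed = config$seed)
            stats_rows[[nm]] <- data.frame(
              table = nm, pseudo_F = pm$pseudo_F, R2 = pm$R2,
              p_value = pm$p_value, n_permutations = pm$n_permutations)
          }
        }
      }
      if (length(stats_rows)) {
        write.table(do.call(rbind, stats_rows),
                    file.path(out_dir, "permanova.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
      }
      manifest$stages$diversity <<- list(n_tables = length(tabs),
                                         n_samples = nrow(rich))
    })
  }

  if ("link" %in% config$stages && !is.null(inputs$species) &&
      !is.null(obu_tables)) {
    run_stage("link", function() {
      md <- inputs$metadata
      all_links <- list()
      all_sum <- list()
      for (dm in names(obu_tables)) {
        niches <- unique(md$source[md$sample_id %in% colnames(obu_tables[[dm]])])
        for (ni in niches) {
          smp <- intersect(md$sample_id[md$source == ni],
                           intersect(colnames(inputs$species),
                                     colnames(obu_tables[[dm]])))
          if (length(smp) < 2) next
          sp <- cm_subset(inputs$species, j = smp)
          ob <- cm_subset(obu_tables[[dm]], j = smp)
          cl <- clean_matrices(sp, ob, min_total = config$min_total)
          dd <- dedup_collinear_species(cl$species)
          if (identical(config$link_scale, "raw")) {
            spn <- dd$species
            obn <- cl$obus
          } else {
            spn <- normalize_counts(dd$species, target = config$norm_target)
            obn <- normalize_counts(cl$obus, target = config$norm_target)
          }
          links <- screen_links(spn, obn, p_threshold = config$p_threshold)
          if (nrow(links)) {
            all_links[[paste(dm, ni)]] <- cbind(domain = dm, niche = ni, links)
          }
          if (!is.null(inputs$taxonomy)) {
            gs <- summarize_by_genus(links, inputs$taxonomy, dd$species)
            all_sum[[paste(dm, ni)]] <- cbind(domain = dm, niche = ni, gs)
          }
        }
      }
      links_df <- if (length(all_links)) do.call(rbind, all_links) else
        data.frame()
      write.table(links_df, file.path(out_dir, "links.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      if (length(all_sum)) {
        write.table(do.call(rbind, all_sum),
                    file.path(out_dir, "genus_summary.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
      }
      manifest$stages$link <<- list(n_links = nrow(links_df))
    })
  }

  if ("recover" %in% config$stages && !is.null(inputs$pdna_tables) &&
      !is.null(obu_tables)) {
    run_stage("recover", function() {
      rows <- list()
      for (dm in intersect(names(obu_tables), names(inputs$pdna_tables))) {
        rows[[dm]] <- obu_recovery_by(obu_tables[[dm]],
                                      inputs$pdna_tables[[dm]],
                                      inputs$metadata, pool_by = "source")
      }
      rec <- do.call(rbind, rows)
      write.table(rec, file.path(out_dir, "recovery.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      manifest$stages$recover <<- list(n_groups = nrow(rec))
    })
  }

  skipped <- setdiff(c("cluster", "diversity", "link", "recover"),
                     names(manifest$stages))
  manifest$skipped_stages <- skipped
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run the synthetic end-to-end demonstration
#'
#' Builds a two-niche (seawater, sediment), three-replicate synthetic
#' survey with planted low-abundance producers, runs every pipeline stage
#' on it, and writes a truth-recovery report comparing the screened links
#' and top genera against the planted ground truth. The demonstration
#' runs the generator's noise-free limit so that, with three replicates
#' per niche (two residual degrees of freedom), planted links are exact
#' fits and pass the p < 0.001 screen; see the methods vignette for why
#' noisy links are undetectable at this design size.
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @return list with the manifest, the truth objects per niche, and the
#'   truth-recovery report, invisibly.
#' @export
demo_synthetic <- function(seed = 1, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  base_seed <- substream_seed(seed, "demo")
  niches <- c(seawater = "W", sediment = "S")

  species_parts <- list()
  obu_parts <- list()
  truths <- list()
  read_parts <- list()
  offset <- 0L
  for (ni in names(niches)) {
    # noise-free limit with an integer slope so all tables stay integer
    # counts and every planted link is an exact fit (see methods vignette)
    cfg <- generator_config(n_samples = 3, n_species = 40, n_producers = 8,
                            obus_per_producer = 2, n_background_obus = 8,
                            count_depth = 100000, nb_dispersion = 0,
                            alpha_range = c(2, 2),
                            low_abundance_fraction = 0.5,
                            seed = base_seed + match(ni, names(niches)))
    com <- generate_community(cfg)
    obu <- generate_obu_counts(com$species, com$truth, cfg)
    # niche-local sample ids and a niche-local OBU namespace
    relabel <- function(ids) sprintf("%s_%s", niches[[ni]], ids)
    sp <- unclass(com$species); colnames(sp) <- relabel(colnames(sp))
    ob <- unclass(obu); colnames(ob) <- relabel(colnames(ob))
    new_obu <- sprintf("OBU_%04d", offset + seq_len(nrow(ob)))
    map <- setNames(new_obu, rownames(ob))
    rownames(ob) <- new_obu
    offset <- offset + nrow(ob)
    tr <- com$truth
    tr$planted_links$obu_id <- unname(map[tr$planted_links$obu_id])
    tr$background_obu_ids <- unname(map[tr$background_obu_ids])
    species_parts[[ni]] <- sp
    obu_parts[[ni]] <- ob
    truths[[ni]] <- tr

    # small read set from the most abundant OBUs to exercise clustering
    sub <- cm_subset(count_matrix(ob, "OBU_KS"),
                     i = seq_len(min(10, nrow(ob))))
    rd <- generate_domain_reads(tr, cfg, sub, max_reads_per_cell = 4)
    read_parts[[ni]] <- rd$reads
    truths[[ni]]$cluster_truth <- rd$truth$cluster_truth
  }

  species <- count_matrix(do.call(cbind, species_parts), "ASV")
  # niche OBU sets are disjoint: absent OBUs count zero in the other niche
  all_obu <- unlist(lapply(obu_parts, rownames), use.names = FALSE)
  samples <- unlist(lapply(obu_parts, colnames), use.names = FALSE)
  obu_m <- matrix(0L, length(all_obu), length(samples),
                  dimnames = list(all_obu, samples))
  for (p in obu_parts) obu_m[rownames(p), colnames(p)] <- p
  obus <- count_matrix(obu_m, "OBU_KS")

  metadata <- data.frame(
    sample_id = colnames(species),
    source = rep(names(niches), each = 3),
    medium = "none",
    replicate = rep(1:3, times = length(niches)),
    stringsAsFactors = FALSE)
  taxonomy <- generate_taxonomy(rownames(species), n_genera = 16,
                                n_orders = 4, seed = seed)

  # cultured fraction: a random subset of eDNA OBUs shows up on plates
  with_rng(base_seed + 77L, {
    pdna_parts <- lapply(names(niches), function(ni) {
      ids <- rownames(obu_parts[[ni]])
      picked <- sort(sample(ids, max(1, round(0.15 * length(ids)))))
      m <- matrix(rnbinom(length(picked) * 2, mu = 30, size = 5) + 1L,
                  length(picked), 2,
                  dimnames = list(picked, sprintf("P%s_%d", niches[[ni]], 1:2)))
      m
    })
  })
  pdna_ids <- unlist(lapply(pdna_parts, rownames), use.names = FALSE)
  pdna_samples <- unlist(lapply(pdna_parts, colnames), use.names = FALSE)
  pdna_m <- matrix(0L, length(pdna_ids), length(pdna_samples),
                   dimnames = list(pdna_ids, pdna_samples))
  for (p in pdna_parts) pdna_m[rownames(p), colnames(p)] <- p
  pdna <- count_matrix(pdna_m, "OBU_KS")
  metadata <- rbind(metadata, data.frame(
    sample_id = pdna_samples,
    source = rep(names(niches), each = 2),
    medium = rep(c("MBA", "MBG"), times = length(niches)),
    replicate = rep(1:2, times = length(niches)),
    stringsAsFactors = FALSE))

  cfg <- run_config(seed = seed, n_perm = 199, link_scale = "raw")
  write_run_config(cfg, file.path(out_dir, "run_config.txt"))
  manifest <- run_all(
    list(read_pairs = list(KS = do.call(rbind, read_parts)),
         species = species, obu_tables = list(KS = obus),
         taxonomy = taxonomy, metadata = metadata,
         pdna_tables = list(KS = pdna)),
    config = cfg, out_dir = out_dir)

  # truth-recovery report: planted links found, producers among top genera
  links_path <- file.path(out_dir, "links.tsv")
  links <- if (file.exists(links_path) && file.size(links_path) > 1) {
    read.delim(links_path, stringsAsFactors = FALSE)
  } else {
    data.frame(niche = character(), obu_id = character(),
               species_id = character(), stringsAsFactors = FALSE)
  }
  report <- lapply(names(niches), function(ni) {
    tr <- truths[[ni]]
    found <- links[links$niche == ni, , drop = FALSE]
    # OBU-level recovery: a planted OBU may legitimately be linked to a
    # species the r^2 = 1 dedup collapsed onto (exact collinearity is
    # common with 3 samples), so identity of the linked species is not
    # required
    planted <- unique(tr$planted_links$obu_id)
    hit <- unique(found$obu_id)
    prod_genera <- unique(taxonomy$genus[match(tr$producer_ids,
                                               taxonomy$feature_id)])
    gs <- read.delim(file.path(out_dir, "genus_summary.tsv"),
                     stringsAsFactors = FALSE)
    gs <- gs[gs$niche == ni, , drop = FALSE]
    top <- gs$genus[order(-gs$n_linked_obus)][seq_len(length(prod_genera))]
    data.frame(niche = ni, n_planted = length(planted),
               n_recovered = sum(planted %in% hit),
               producer_genera_in_top =
                 sum(prod_genera %in% top) / length(prod_genera),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, report)
  write.table(report, file.path(out_dir, "truth_recovery.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(manifest = manifest, truths = truths, report = report))
}
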