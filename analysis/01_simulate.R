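#!/usr/bin/env Rscript

# Simulate a two-niche (seawater/sediment), three-replicate amplicon survey
# with planted low-abundance producers, and write every table the rest of
# the workflow consumes. The noise-free co-occurrence limit with an integer
# slope is used so that downstream linking has an exact planted truth.

library(obulink)

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

niches <- c(seawater = "W", sediment = "S")
species_parts <- list(); obu_parts <- list(); truth_rows <- list()
offset <- 0L

for (ni in names(niches)) {
  cfg <- generator_config(n_samples = 3, n_species = 60, n_producers = 10,
                          obus_per_producer = 2, n_background_obus = 10,
                          count_depth = 100000, nb_dispersion = 0,
                          alpha_range = c(2, 2), low_abundance_fraction = 0.5,
                          seed = seed + match(ni, names(niches)))
  com <- generate_community(cfg)
  obu <- generate_obu_counts(com$species, com$truth, cfg)

  sp <- unclass(com$species)
  colnames(sp) <- sprintf("%s_%s", niches[[ni]], colnames(sp))
  ob <- unclass(obu)
  colnames(ob) <- sprintf("%s_%s", niches[[ni]], colnames(ob))
  new_ids <- sprintf("OBU_%04d", offset + seq_len(nrow(ob)))
  map <- setNames(new_ids, rownames(ob))
  rownames(ob) <- new_ids
  offset <- offset + nrow(ob)

  species_parts[[ni]] <- sp
  obu_parts[[ni]] <- ob
  tr <- com$truth$planted_links
  tr$obu_id <- unname(map[tr$obu_id])
  tr$niche <- ni
  tr$low_abundance <- tr$species_id %in% com$truth$low_abundance_ids
  truth_rows[[ni]] <- tr
}

species <- count_matrix(do.call(cbind, species_parts), "ASV")
all_obu <- unlist(lapply(obu_parts, rownames), use.names = FALSE)
samples <- unlist(lapply(obu_parts, colnames), use.names = FALSE)
obu_m <- matrix(0L, length(all_obu), length(samples),
                dimnames = list(all_obu, samples))
for (p in obu_parts) obu_m[rownames(p), colnames(p)] <- p
obus <- count_matrix(obu_m, "OBU_KS")

metadata <- data.frame(sample_id = colnames(species),
                       source = rep(names(niches), each = 3),
                       medium = "none", replicate = rep(1:3, 2))
taxonomy <- generate_taxonomy(rownames(species), n_genera = 25, n_orders = 6,
                              seed = seed)
truth <- do.call(rbind, truth_rows)

write_count_table(species, file.path(out, "species_table.tsv"))
write_count_table(obus, file.path(out, "obu_ks_table.tsv"),
                  id_column = "obu_id")
write_taxonomy(taxonomy, file.path(out, "taxonomy.tsv"))
write_sample_metadata(metadata, file.path(out, "metadata.tsv"))
write.table(truth, file.path(out, "planted_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d species x %d samples; %d OBUs (%d planted links)\n",
            nrow(species), ncol(species), nrow(obus), nrow(truth)))
cat(sprintf("low-abundance producers (<0.1%% rel. abundance): %d\n",
            sum(truth$low_abundance[!duplicated(truth$species_id)])))
cat("tables written under", out, "\n")
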