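#!/usr/bin/env Rscript
# Stage 1: generate the study's synthetic runs.
#
# Two references (mid- and low-G+C, standing in for the two template
# species), planted high-frequency indel sites, and four sequencing runs
# spanning the kit/chip factor levels. Everything downstream (error
# profiles, HFI detection, DGLM, G+C bias, trimming) reads these files.

suppressMessages(library(ionflow))

seed <- 20260927L
out <- file.path("results", "sim")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# 10 kb references give 30-50x coverage per run, enough for site-level
# (HFI) testing; the six runs span species x chip x kit so every factor
# level is identifiable in the DGLM
genomes <- list(
  B.amyloliquefaciens = simulate_reference(10000, gc_target = 0.461,
                                           seed = seed),
  S.tokodaii = simulate_reference(10000, gc_target = 0.328, seed = seed + 1L))

runs <- list(
  list(id = "314-B-100", species = "B.amyloliquefaciens", chip = "314",
       kit = "OT100", len = 100L, n = 3000L),
  list(id = "316-S-100", species = "S.tokodaii", chip = "316",
       kit = "OT100", len = 100L, n = 3000L),
  list(id = "314-B-200", species = "B.amyloliquefaciens", chip = "314",
       kit = "OT200", len = 200L, n = 2000L),
  list(id = "316-B-200M", species = "B.amyloliquefaciens", chip = "316",
       kit = "M200", len = 200L, n = 2000L),
  list(id = "314-S-200M", species = "S.tokodaii", chip = "314",
       kit = "M200", len = 200L, n = 2000L),
  list(id = "316-S-200", species = "S.tokodaii", chip = "316",
       kit = "OT200", len = 200L, n = 2000L))

manifest <- list()
for (i in seq_along(runs)) {
  r <- runs[[i]]
  g <- genomes[[r$species]]
  # HFI sites are largely run-private artifacts: plant an independent set
  # per run at ~1 per 2000 bp
  hfi <- plant_hfi_sites(g, hfi_rate = 5e-4, penetrance = 0.3,
                         asym_fraction = 0.1, seed = seed + 10L * i)
  cfg <- sim_config(n_reads = r$n, read_len_bases = r$len,
                    metadata = run_metadata(r$id, chip = r$chip, kit = r$kit,
                                            species_label = r$species),
                    sub_rate = 5e-4, seed = seed + 100L * i)
  sim <- simulate_run(g, hfi, cfg, contig_name = r$species)
  paths <- write_sim(sim, out, r$id)
  data.table::fwrite(hfi, file.path(out, paste0(r$id, "_hfi_truth.tsv")),
                     sep = "\t")
  manifest[[r$id]] <- data.table::data.table(
    run = r$id, n_reads = r$n, kit = r$kit, chip = r$chip,
    species = r$species, seed = cfg$seed)
  cat(sprintf("%s: %d reads, %d planted HFI sites\n", r$id, r$n, nrow(hfi)))
}
data.table::fwrite(data.table::rbindlist(manifest),
                   file.path(out, "runs_manifest.tsv"), sep = "\t")
cat("simulation written under", out, "\n")
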