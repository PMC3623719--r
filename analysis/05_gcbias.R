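#!/usr/bin/env Rscript
# Stage 5: G+C coverage bias.
#
# Computes disjoint 100 bp window G+C and coverage per run (repeat- and
# end-masked), run-normalises, square-root transforms, and fits the linear
# model with species interaction, reported as one regression per species.

suppressMessages(library(ionflow))

sim_dir <- file.path("results", "sim")
prof_dir <- file.path("results", "profiles")
out <- file.path("results", "gcbias")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

manifest <- data.table::fread(file.path(sim_dir, "runs_manifest.tsv"))
windows <- list()
for (i in seq_len(nrow(manifest))) {
  run_id <- manifest$run[i]
  sam <- read_sam(file.path(sim_dir, paste0(run_id, ".sam")))
  fa <- read_fasta(file.path(sim_dir, paste0(run_id, ".fasta")))
  repeats <- read_bed_mask(file.path(prof_dir,
                                     paste0(run_id, "_repeats.bed")))
  ws <- window_stats(sam$records, fa[[1]], mask = repeats,
                     species = manifest$species[i],
                     contig = names(fa)[1])
  ws[, run := run_id]
  windows[[run_id]] <- ws
}
recs <- normalise_and_transform(data.table::rbindlist(windows),
                                drop_outliers = TRUE)
data.table::fwrite(recs, file.path(out, "windows.tsv"), sep = "\t")
fit <- fit_gc_model(recs)
print(fit)
data.table::fwrite(fit$per_species, file.path(out, "gc_model.tsv"),
                   sep = "\t")
resid_dt <- data.table::data.table(fitted = stats::fitted(fit$model),
                                   residual = stats::resid(fit$model))
data.table::fwrite(resid_dt, file.path(out, "residuals.tsv"), sep = "\t")
cat("G+C bias results written under", out, "\n")
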