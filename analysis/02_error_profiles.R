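#!/usr/bin/env Rscript
# Stage 2: base- and flow-level error profiles per run.
#
# Reads each simulated run's SFF + SAM + FASTA, masks perfect-match
# repeats, classifies alignment columns, projects them onto flows, and
# writes the error summaries: rates by type and by base position,
# homopolymer-length accuracy, PIC-resolved indel rates, the substitution
# spectrum, zero-flow over-call rates, start-position uniformity and
# over-long read flags.

suppressMessages(library(ionflow))

sim_dir <- file.path("results", "sim")
out <- file.path("results", "profiles")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

manifest <- data.table::fread(file.path(sim_dir, "runs_manifest.tsv"))
for (i in seq_len(nrow(manifest))) {
  run_id <- manifest$run[i]
  kit <- manifest$kit[i]
  sff <- read_sff(file.path(sim_dir, paste0(run_id, ".sff")))
  sam <- read_sam(file.path(sim_dir, paste0(run_id, ".sam")))
  genome <- read_fasta(file.path(sim_dir, paste0(run_id, ".fasta")))[[1]]
  contig <- names(read_fasta(file.path(sim_dir, paste0(run_id, ".fasta"))))[1]
  repeats <- find_exact_repeats(genome, 30L, contig = contig)
  write_bed_mask(repeats, file.path(out, paste0(run_id, "_repeats.bed")))

  pr <- profile_run(sff, sam, genome, kit = kit, mask = repeats,
                    contig = contig)
  br <- base_error_rates(pr$columns)
  fr <- flow_error_rates(pr$observations)
  sp <- substitution_spectrum(pr$columns)
  w <- function(x, nm) data.table::fwrite(
    x, file.path(out, paste0(run_id, "_", nm, ".tsv")), sep = "\t")
  w(br$rates, "base_rates")
  w(br$by_position, "base_rates_by_position")
  w(fr$by_h, "hp_accuracy")
  w(fr$by_pic, "pic_rates")
  w(fr$by_flow, "flow_rates")
  w(fr$zero_by_pic_cycle, "zero_overcall")
  w(sp, "substitution_spectrum")

  starts <- data.table::data.table(start = sam$records$pos,
                                   strand = sam$records$strand)
  u <- start_uniformity(starts, nchar(genome), mask = repeats,
                        contig = contig)
  lens <- nchar(vapply(sff$reads, `[[`, character(1), "bases"))
  flags <- flag_overlong_reads(lens, kit)
  cat(sprintf(
    "%s: %.3f%% ins, %.3f%% del, %.3f%% sub | start-uniformity p = %.3f | %d over-long reads\n",
    run_id,
    100 * br$rates[br$rates$type == "ins"]$rate,
    100 * br$rates[br$rates$type == "del"]$rate,
    100 * br$rates[br$rates$type == "sub"]$rate,
    u$p_value, sum(flags)))
}
cat("profiles written under", out, "\n")
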