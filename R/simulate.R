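# Synthetic-data generators. All randomness flows from one user seed through
# named substreams so each stage is independently reproducible.

substream_seed <- function(seed, name) {
  as.integer((as.double(seed) %% 65536 * 32749 +
                sum(utf8ToInt(name)) * 104729) %% 2147483629)
}

#' Simulation configuration for a flowgram run
#'
#' Bundles the generative settings of one simulated sequencing run. The
#' defaults emulate a 100 bp OneTouch run on a 314 chip: flow-values are
#' Gaussian with mean and log-variance linear in homopolymer length, cycle
#' and run factors ([pgm_flow_model()]); zero-length homopolymer flows
#' follow a truncated Gaussian whose defaults put zero-mer call accuracy in
#' the observed 98.75-99.72% band; substitutions carry the low-confidence
#' 0.51 flow-value signature; high-frequency indel (HFI) sites are planted
#' as template edits with configurable penetrance and strand restriction.
#'
#' @param n_reads Number of reads to simulate.
#' @param read_len_bases Target called read length (the kit's nominal
#'   length); the flow budget is `flows_per_base * read_len_bases`, rounded
#'   up to whole cycles.
#' @param flow_order A [flow_order] (default Samba, period 32).
#' @param key Key sequence prepended to every template (default "TACG");
#'   key flows are synthesised noise-free (the instrument normalises
#'   flow-values to the key).
#' @param metadata A [run_metadata] giving the run's factor levels.
#' @param mean_params,disp_params [dglm_params] for the flow-value mean and
#'   log-variance (defaults: the fitted PGM model, PIC effects zero).
#' @param zero_flow Length-2 numeric `(mean, sd)` of the truncated Gaussian
#'   for true zero-length homopolymer flows.
#' @param sub_rate Per-aligned-base substitution probability.
#' @param hfi_penetrance Default proportion of covering reads affected by a
#'   planted HFI site.
#' @param flows_per_base Flow budget per target base (default 1.6;
#'   near-random sequence consumes about 1.68 flows per base under the
#'   Samba order).
#' @param quality_map Function mapping absolute flow residual (|value -
#'   called length|) to an integer Phred score.
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_reads = 1000L, read_len_bases = 100L,
                       flow_order = samba_order(), key = "TACG",
                       metadata = run_metadata("sim"),
                       mean_params = pgm_flow_model()$mean,
                       disp_params = pgm_flow_model()$dispersion,
                       zero_flow = c(mean = 0.12, sd = 0.15),
                       sub_rate = 5e-4, hfi_penetrance = 0.3,
                       flows_per_base = 1.6,
                       quality_map = default_quality_map,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory (no implicit entropy)")
  stopifnot(n_reads >= 1, read_len_bases >= 10, sub_rate >= 0,
            sub_rate <= 1, hfi_penetrance >= 0, hfi_penetrance <= 1,
            zero_flow[["sd"]] > 0)
  P <- flow_order$period
  n_flows <- as.integer(ceiling(read_len_bases * flows_per_base / P) * P)
  structure(list(n_reads = as.integer(n_reads),
                 read_len_bases = as.integer(read_len_bases),
                 flow_order = flow_order, key = key, metadata = metadata,
                 mean_params = mean_params, disp_params = disp_params,
                 zero_flow = zero_flow, sub_rate = sub_rate,
                 hfi_penetrance = hfi_penetrance, n_flows = n_flows,
                 quality_map = quality_map, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default residual-to-quality map
#'
#' Monotone decreasing in the absolute flow residual; a residual of 0.49
#' (the 0.51 substitution signature on a 1-mer) maps to Phred 11.
#' @param resid Absolute flow residuals in [0, 0.5].
#' @return Integer Phred scores.
#' @export
default_quality_map <- function(resid) {
  pmax(5L, pmin(33L, as.integer(round(33 - 45 * resid))))
}

#' Simulate a reference contig with a target G+C content
#'
#' Bases are i.i.d. with P(G) = P(C) = `gc_target / 2`.
#' @param length Contig length in bp.
#' @param gc_target Target G+C proportion in (0, 1).
#' @param seed Integer seed.
#' @return A single uppercase sequence string with attribute `name`.
#' @export
simulate_reference <- function(length, gc_target = 0.45, seed) {
  stopifnot(gc_target > 0, gc_target < 1, length >= 1)
  set.seed(substream_seed(seed, "genome"))
  p <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
         G = gc_target / 2, T = (1 - gc_target) / 2)
  seq <- paste(sample(names(p), length, replace = TRUE, prob = p),
               collapse = "")
  attr(seq, "name") <- "sim_contig"
  seq
}

#' Plant high-frequency indel (HFI) sites in a genome
#'
#' Sites are drawn uniformly, at most one per homopolymer run, and assigned
#' a type (insertion = duplication of the site's base, biased towards A/T;
#' deletion = removal of one base from a run of length >= 2, biased towards
#' C/G), a penetrance, and an optional strand restriction. Edits are
#' single-base and stay inside an existing run, so the flow structure of
#' affected reads is preserved.
#'
#' @param genome Reference sequence string.
#' @param hfi_rate Expected sites per reference bp.
#' @param penetrance Proportion of covering reads carrying the edit.
#' @param asym_fraction Probability a site is restricted to one strand.
#' @param at_bias Probability an insertion site is drawn from A/T positions
#'   (and a deletion site from C/G runs).
#' @param seed Integer seed.
#' @return `data.table` with columns pos (1-based), type ("ins"/"del"),
#'   base, penetrance, strand (NA, "+" or "-").
#' @export
plant_hfi_sites <- function(genome, hfi_rate = 1e-3, penetrance = 0.3,
                            asym_fraction = 0.1, at_bias = 0.8, seed) {
  stopifnot(hfi_rate >= 0, hfi_rate <= 1)
  set.seed(substream_seed(seed, "hfi"))
  L <- nchar(genome)
  n_sites <- stats::rbinom(1L, L, hfi_rate)
  empty <- data.table::data.table(pos = integer(0), type = character(0),
                                  base = character(0),
                                  penetrance = numeric(0),
                                  strand = character(0))
  if (n_sites == 0L) return(empty)
  chars <- strsplit(genome, "")[[1]]
  r <- rle(chars)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  run_len <- rep(r$lengths, r$lengths)
  if (n_sites > length(r$lengths) / 4)
    stop("hfi_rate too high: collisions between sites unavoidable")
  is_ins <- stats::runif(n_sites) < 0.5
  used_runs <- integer(0)
  out <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    if (is_ins[i]) {
      want <- if (stats::runif(1) < at_bias) c("A", "T") else c("C", "G")
      ok <- chars %in% want & !(run_id %in% used_runs)
    } else {
      want <- if (stats::runif(1) < at_bias) c("C", "G") else c("A", "T")
      ok <- chars %in% want & run_len >= 2L & !(run_id %in% used_runs)
      if (!any(ok))  # fall back to any deletable run
        ok <- run_len >= 2L & !(run_id %in% used_runs)
    }
    if (!any(ok)) stop("no eligible positions left for HFI site ", i)
    pos <- sample(which(ok), 1L)
    used_runs <- c(used_runs, run_id[pos])
    out[[i]] <- data.table::data.table(
      pos = pos, type = if (is_ins[i]) "ins" else "del",
      base = chars[pos], penetrance = penetrance,
      strand = if (stats::runif(1) < asym_fraction)
        sample(c("+", "-"), 1L) else NA_character_)
  }
  data.table::rbindlist(out)[order(pos)]
}

#' Simulate flow observations directly from the DGLM generative model
#'
#' Draws flow-values `y ~ Normal(mu, sigma^2)` with `mu` and `log sigma^2`
#' given by the two linear predictors, without the read-level machinery.
#' This is the input for parameter-recovery experiments: homopolymer
#' lengths uniform on `h_range`, cycles uniform on `cycle_range`, factor
#' levels balanced over species x chip x kit.
#'
#' @param n Number of observations.
#' @param mean_params,disp_params [dglm_params].
#' @param h_range,cycle_range Integer vectors to sample h and cycle from.
#' @param seed Integer seed.
#' @return `data.table` with columns y, h, cycle, pic, species, chip, kit.
#' @export
simulate_flow_observations <- function(n, mean_params = pgm_flow_model()$mean,
                                       disp_params = pgm_flow_model()$dispersion,
                                       h_range = 1:5, cycle_range = 0:13,
                                       seed) {
  set.seed(substream_seed(seed, "obs"))
  combos <- expand.grid(species = c("B.amyloliquefaciens", "S.tokodaii"),
                        chip = c("314", "316"),
                        kit = c("OT100", "M200", "OT200"),
                        stringsAsFactors = FALSE)
  idx <- rep_len(sample(nrow(combos)), n)
  dt <- data.table::data.table(
    h = sample(h_range, n, replace = TRUE),
    cycle = sample(cycle_range, n, replace = TRUE),
    pic = 0L,
    species = combos$species[idx], chip = combos$chip[idx],
    kit = combos$kit[idx])
  mu <- eval_predictor(mean_params, dt$h, dt$cycle, dt$pic,
                       dt$species, dt$chip, dt$kit)
  sigma <- sqrt(exp(eval_predictor(disp_params, dt$h, dt$cycle, dt$pic,
                                   dt$species, dt$chip, dt$kit)))
  dt[, y := stats::rnorm(n, mu, sigma)]
  data.table::setcolorder(dt, "y")
  dt[]
}

#' Simulate per-site pileups for HFI detector calibration
#'
#' Generates site-level difference counts directly (without reads): at each
#' reference position, per-strand coverage and binomial counts of
#' substitution and indel differences at homopolymer-length-dependent null
#' rates; optionally planted HFI sites with elevated (penetrance) rates and
#' strand restriction.
#'
#' @param genome Reference sequence string (drives the per-site
#'   homopolymer length).
#' @param coverage Mean per-strand-pair coverage (total coverage at a site
#'   is split evenly between strands).
#' @param sub_rate Null substitution rate per covering read.
#' @param indel_rate_base Null indel rate for a 1-mer; the per-h null rate
#'   is `indel_rate_base * h` (indel error grows with homopolymer length).
#' @param planted Optional `data.table` from [plant_hfi_sites()].
#' @param seed Integer seed.
#' @return `data.table` with one row per unmasked position: pos, h,
#'   cov_fwd, cov_rev, sub_fwd, sub_rev, ins_fwd, ins_rev, del_fwd,
#'   del_rev.
#' @export
simulate_site_pileups <- function(genome, coverage = 100, sub_rate = 2e-4,
                                  indel_rate_base = 1.5e-3, planted = NULL,
                                  seed) {
  set.seed(substream_seed(seed, "pileup"))
  chars <- strsplit(genome, "")[[1]]
  r <- rle(chars)
  h <- rep(r$lengths, r$lengths)
  L <- length(chars)
  cov_f <- pmax(1L, stats::rpois(L, coverage / 2))
  cov_r <- pmax(1L, stats::rpois(L, coverage / 2))
  p_ind <- indel_rate_base * h
  dt <- data.table::data.table(
    pos = seq_len(L), h = h, cov_fwd = cov_f, cov_rev = cov_r,
    sub_fwd = stats::rbinom(L, cov_f, sub_rate),
    sub_rev = stats::rbinom(L, cov_r, sub_rate),
    ins_fwd = stats::rbinom(L, cov_f, p_ind),
    ins_rev = stats::rbinom(L, cov_r, p_ind),
    del_fwd = stats::rbinom(L, cov_f, p_ind),
    del_rev = stats::rbinom(L, cov_r, p_ind))
  if (!is.null(planted) && nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      p <- planted$pos[i]
      col <- if (planted$type[i] == "ins") "ins" else "del"
      pen <- planted$penetrance[i]
      on_f <- is.na(planted$strand[i]) || planted$strand[i] == "+"
      on_r <- is.na(planted$strand[i]) || planted$strand[i] == "-"
      if (on_f) dt[p, (paste0(col, "_fwd")) :=
                     get(paste0(col, "_fwd")) +
                     stats::rbinom(1L, cov_fwd, pen)]
      if (on_r) dt[p, (paste0(col, "_rev")) :=
                     get(paste0(col, "_rev")) +
                     stats::rbinom(1L, cov_rev, pen)]
    }
    dt[, ins_fwd := pmin(ins_fwd, cov_fwd)]
    dt[, ins_rev := pmin(ins_rev, cov_rev)]
    dt[, del_fwd := pmin(del_fwd, cov_fwd)]
    dt[, del_rev := pmin(del_rev, cov_rev)]
  }
  dt[]
}

#' Simulate window coverage with a planted linear G+C effect
#'
#' Generates disjoint-window records whose square-root run-normalised
#' coverage is linear in window G+C with Gaussian noise:
#' `sqrt(cov / mean_cov) = intercept + slope * gc + e`. Used for
#' slope-recovery calibration of the G+C bias regression.
#'
#' @param n_windows Number of 100 bp windows.
#' @param intercept,slope Coefficients on the square-root normalised scale.
#' @param noise_sd Gaussian noise s.d. on the same scale.
#' @param mean_cov Mean per-window raw coverage.
#' @param gc_range Range to draw window G+C proportions from.
#' @param species Species label attached to every window.
#' @param seed Integer seed.
#' @return `data.table` with columns contig, start, gc, raw_cov, species.
#' @export
simulate_window_coverage <- function(n_windows = 500L, intercept = 0.6745,
                                     slope = 0.8, noise_sd = 0.05,
                                     mean_cov = 50, gc_range = c(0.2, 0.6),
                                     species = "B.amyloliquefaciens", seed) {
  set.seed(substream_seed(seed, "gc"))
  gc <- stats::runif(n_windows, gc_range[1], gc_range[2])
  s <- intercept + slope * gc + stats::rnorm(n_windows, 0, noise_sd)
  data.table::data.table(
    contig = "sim_contig",
    start = seq.int(1L, by = 100L, length.out = n_windows),
    gc = gc, raw_cov = mean_cov * pmax(s, 0)^2, species = species)
}
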