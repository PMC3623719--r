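#' Per-window G+C and coverage statistics
#'
#' Splits the reference into disjoint 100 bp windows, computes each
#' window's G+C proportion and mean per-base read coverage from the
#' alignment reference spans (deleted reference bases remain covered;
#' insertions add no depth). Windows overlapping the excluded reference
#' ends (120 bp) or containing any masked base are dropped entirely.
#'
#' @param sam_records Mapped SAM records (pos, ref_width).
#' @param genome Reference sequence string.
#' @param window Window width in bp (default 100).
#' @param mask Optional [mask_set] (repeats, HFI sites, outlier regions).
#' @param end_exclusion Reference bases excluded at each end (default 120).
#' @param species Species label attached to every window.
#' @param contig Contig name.
#' @param mask_overlap_frac A window is excluded when more than this
#'   fraction of its bases is masked (default 0: any masked base excludes
#'   the window).
#' @return `data.table`: contig, start, gc, raw_cov, species.
#' @export
window_stats <- function(sam_records, genome, window = 100L, mask = NULL,
                         end_exclusion = 120L,
                         species = "B.amyloliquefaciens",
                         contig = "sim_contig", mask_overlap_frac = 0) {
  L <- nchar(genome)
  cov <- as.integer(IRanges::coverage(
    IRanges::IRanges(sam_records$pos, width = sam_records$ref_width),
    width = L))
  starts <- seq.int(1L, L - window + 1L, by = window)
  keep <- starts > end_exclusion & (starts + window - 1L) <= L - end_exclusion
  starts <- starts[keep]
  if (length(starts) < 3L) stop("fewer than 3 windows after end exclusion")
  chars <- strsplit(toupper(genome), "")[[1]]
  isgc <- chars %in% c("G", "C")
  cumgc <- cumsum(isgc)
  cumcov <- cumsum(as.numeric(cov))
  gc <- (cumgc[starts + window - 1L] - cumgc[starts - 1L]) / window
  raw <- (cumcov[starts + window - 1L] - cumcov[starts - 1L]) / window
  dt <- data.table::data.table(contig = contig, start = starts, gc = gc,
                               raw_cov = raw, species = species)
  if (!is.null(mask) && nrow(mask)) {
    bits <- mask_bits(mask, contig, L)
    cumm <- cumsum(bits)
    mfrac <- (cumm[starts + window - 1L] - cumm[starts - 1L]) / window
    dt <- dt[mfrac <= mask_overlap_frac]
  }
  if (nrow(dt) < 3L) stop("fewer than 3 windows after masking")
  dt[]
}

#' Run-normalise window coverage and apply the square-root transform
#'
#' Coverage in each window is divided by the mean coverage across all
#' windows of that run (so the per-run mean of the normalised coverage is
#' exactly 1), then square-root transformed: `y = sqrt(norm_cov)`, the
#' fold-change scale on which a value of 2 means four times the mean
#' coverage. Extreme windows (normalised coverage above
#' median + 10 * MAD, e.g. unmasked rRNA repeats) are flagged and can be
#' excluded before modelling.
#'
#' @param records Window table from [window_stats()] (a `run` column
#'   groups multi-run input; otherwise one run is assumed).
#' @param drop_outliers Exclude flagged windows (default FALSE; they are
#'   always flagged in the `outlier` column).
#' @param outlier_mads MAD multiplier for the outlier cut (default 10).
#' @return The table with added columns norm_cov, y, outlier.
#' @export
normalise_and_transform <- function(records, drop_outliers = FALSE,
                                    outlier_mads = 10) {
  dt <- data.table::as.data.table(records)
  if (!"run" %in% names(dt)) dt[, run := "run1"]
  if (any(dt[, .(m = mean(raw_cov)), by = run]$m <= 0))
    stop("zero mean coverage in at least one run")
  dt[, norm_cov := raw_cov / mean(raw_cov), by = run]
  dt[, y := sqrt(norm_cov)]
  dt[, outlier := norm_cov > stats::median(norm_cov) +
       outlier_mads * stats::mad(norm_cov), by = run]
  if (drop_outliers) dt <- dt[outlier == FALSE]
  dt[]
}

#' Fit the G+C coverage-bias regression
#'
#' Linear model of the square-root run-normalised coverage on window G+C,
#' with a species main effect and G+C-by-species interaction when several
#' species are present. The model is reported split into one regression
#' (intercept + slope) per species.
#'
#' @param records Output of [normalise_and_transform()].
#' @param min_windows Minimum windows required per species (default 30).
#' @return A `gc_fit`: list with `model` (the `lm`), `per_species`
#'   (`data.table`: species, intercept, slope, n), `r_squared`, and
#'   `residual_summary`.
#' @export
fit_gc_model <- function(records, min_windows = 30L) {
  dt <- data.table::as.data.table(records)
  stopifnot(all(c("y", "gc", "species") %in% names(dt)))
  cnt <- dt[, .N, by = species]
  if (any(cnt$N < min_windows))
    stop("need at least ", min_windows, " windows per species")
  if (stats::var(dt$gc) == 0)
    stop("no variation in window G+C; slope is unidentifiable")
  multi <- length(unique(dt$species)) > 1L
  model <- if (multi) stats::lm(y ~ gc * species, data = dt)
           else stats::lm(y ~ gc, data = dt)
  cf <- stats::coef(model)
  per_species <- data.table::rbindlist(lapply(
    sort(unique(dt$species)), function(sp) {
      a <- cf[["(Intercept)"]]
      b <- cf[["gc"]]
      nm_a <- paste0("species", sp)
      nm_b <- paste0("gc:species", sp)
      if (nm_a %in% names(cf)) a <- a + cf[[nm_a]]
      if (nm_b %in% names(cf)) b <- b + cf[[nm_b]]
      data.table::data.table(species = sp, intercept = a, slope = b,
                             n = sum(dt$species == sp))
    }))
  structure(list(model = model, per_species = per_species,
                 r_squared = summary(model)$r.squared,
                 residual_summary = summary(stats::resid(model))),
            class = "gc_fit")
}

#' @export
print.gc_fit <- function(x, ...) {
  cat("<gc_fit> R^2 =", signif(x$r_squared, 4), "\n")
  print(x$per_species)
  invisible(x)
}
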