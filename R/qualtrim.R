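#' Empirical recalibration of assigned quality scores
#'
#' For each assigned Phred score, the observed error rate of bases carrying
#' that score and the corresponding empirical Phred value
#' (q = -10 log10(p_error)). Qualities can only flag inserted and
#' substituted bases, so deletion columns are excluded. Cells with zero
#' observed errors report the rule-of-three bound -10 log10(3 / n),
#' flagged as a bound.
#'
#' @param columns Bound column table (with `name`) from [profile_run()].
#' @param sff Output of [read_sff()] (source of per-base qualities).
#' @return `data.table`: q, n, errors, empirical_q, is_bound.
#' @export
empirical_quality <- function(columns, sff) {
  qual_by_name <- stats::setNames(lapply(sff$reads, `[[`, "qualities"),
                                  vapply(sff$reads, `[[`, character(1),
                                         "name"))
  cols <- columns[columns$kind != "del"]
  q <- unlist(Map(function(nm, pos) qual_by_name[[nm]][pos],
                  cols$name, cols$read_pos), use.names = FALSE)
  err <- cols$kind %in% c("sub", "ins")
  dt <- data.table::data.table(q = q, err = err)
  out <- dt[, .(n = .N, errors = sum(err)), by = q]
  out[, is_bound := errors == 0L]
  out[, empirical_q := ifelse(errors > 0L, -10 * log10(errors / n),
                              -10 * log10(3 / n))]
  data.table::setorder(out, q)
  out[]
}

#' Quality change along homopolymers, correct versus over-called
#'
#' Samples reads and, within every called homopolymer (flow with called
#' length >= 2), computes the relative change in quality from the first
#' base to each later base: (q(base 1) - q(base x)) / q(base 1), split by
#' whether the flow was called correctly or over-called. Rows with
#' q(base 1) = 0 are excluded and counted.
#'
#' @param observations Flow-observation table with name, flow, h_true,
#'   h_called.
#' @param sff Output of [read_sff()].
#' @param n_sample Number of reads to sample (default 20000).
#' @param seed Integer seed for the read sample.
#' @return List with `profile` (`data.table`: pos_in_hp, group, mean
#'   relative change, n) and `n_excluded_q0`.
#' @export
hp_quality_profile <- function(observations, sff, n_sample = 20000L, seed) {
  set.seed(substream_seed(seed, "hp_quality"))
  nms <- unique(observations$name)
  nms <- sample(nms, min(n_sample, length(nms)))
  obs <- observations[observations$name %in% nms &
                        observations$h_called >= 2L &
                        observations$h_called >= observations$h_true &
                        observations$sub == FALSE]
  reads <- stats::setNames(sff$reads,
                           vapply(sff$reads, `[[`, character(1), "name"))
  rows <- vector("list", nrow(obs))
  n_q0 <- 0L
  for (i in seq_len(nrow(obs))) {
    rd <- reads[[obs$name[i]]]
    qs <- rd$qualities[rd$flow_of_base == obs$flow[i]]
    if (length(qs) < 2L) next
    if (qs[1] == 0L) { n_q0 <- n_q0 + 1L; next }
    rows[[i]] <- data.table::data.table(
      pos_in_hp = seq_along(qs),
      rel_change = (qs[1] - qs) / qs[1],
      group = if (obs$h_called[i] > obs$h_true[i]) "over_call" else
        "correct")
  }
  long <- data.table::rbindlist(rows)
  profile <- if (nrow(long))
    long[, .(mean_rel_change = mean(rel_change), n = .N),
         by = .(pos_in_hp, group)]
  else data.table::data.table(pos_in_hp = integer(0), group = character(0),
                              mean_rel_change = numeric(0), n = integer(0))
  data.table::setorder(profile, group, pos_in_hp)
  list(profile = profile[], n_excluded_q0 = n_q0)
}

#' Effective quality/adapter clip of an SFF read
#'
#' SFF clip fields are 1-based inclusive with 0 meaning unset; when both
#' quality and adapter clips are present the more stringent is used. When
#' neither is set and `qt_fallback` is TRUE, a windowed quality trim is
#' applied instead: the read is clipped at the first 30 bp window with
#' mean quality of 9 or less.
#'
#' @param sff_read One read record from [read_sff()].
#' @param qt_fallback Apply the Q9/30 bp windowed rule when no clip is
#'   stored (default TRUE).
#' @return Integer `c(start, end)`: retained bases, 1-based inclusive
#'   (end 0 means the whole read is clipped away).
#' @export
effective_clip <- function(sff_read, qt_fallback = TRUE) {
  nb <- nchar(sff_read$bases)
  cq <- sff_read$clip_qual
  ca <- sff_read$clip_adapter
  left <- max(1L, cq[1], ca[1])
  rights <- c(if (cq[2] > 0L) cq[2], if (ca[2] > 0L) ca[2])
  right <- if (length(rights)) min(rights, nb) else nb
  if (all(cq == 0L) && all(ca == 0L) && qt_fallback && nb >= 30L) {
    q <- sff_read$qualities
    wmean <- (cumsum(q)[30:nb] -
                c(0, cumsum(q))[1:(nb - 29L)]) / 30
    bad <- which(wmean <= 9)
    if (length(bad)) right <- min(right, bad[1] - 1L)
  }
  c(left, max(right, 0L))
}

hri_ranges <- list(
  `1` = rbind(c(50L, 59L), c(140L, 149L)),
  `2` = rbind(c(150L, 159L), c(241L, 249L)),
  `3` = rbind(c(250L, 259L), c(340L, 349L)))

is_hri_flow <- function(v100, hc, include_3mers = FALSE) {
  in_r <- function(r) (v100 >= r[1, 1] & v100 <= r[1, 2]) |
    (v100 >= r[2, 1] & v100 <= r[2, 2])
  hri <- (hc == 1L & in_r(hri_ranges[["1"]])) |
    (hc == 2L & in_r(hri_ranges[["2"]]))
  if (include_3mers) hri <- hri | (hc == 3L & in_r(hri_ranges[["3"]]))
  hri
}

#' High-residual ionogram (HRI) 3' trimming
#'
#' Emulates the flow-based quality trim: flows are removed one at a time
#' from the 3' end until the percentage of HRI 1-mers and 2-mers among all
#' 1-mer and 2-mer calls in the retained read is 3% or less (the totals
#' are recomputed on the retained prefix at every step). A high-residual
#' 1-mer has a flow-value in [0.50, 0.59] or [1.40, 1.49]; a 2-mer in
#' [1.50, 1.59] or [2.41, 2.49]; with `include_3mers`, 3-mers in
#' [2.50, 2.59] or [3.40, 3.49] join both numerator and denominator.
#' Range membership is exact on the hundredth grid.
#'
#' @param sff_read One read record from [read_sff()] (fields `values`,
#'   `flow_of_base`, `bases`).
#' @param include_3mers Include 3-mer HRI flows (default FALSE).
#' @param max_frac HRI fraction threshold (default 0.03).
#' @return List with `clip` (`c(1, n_bases_retained)`, 1-based inclusive),
#'   `flows_retained`, and `discarded` (TRUE when fewer than 4 bases
#'   remain).
#' @export
hri_trim <- function(sff_read, include_3mers = FALSE, max_frac = 0.03) {
  v100 <- as.integer(round(sff_read$values * 100))
  nf <- length(v100)
  hc <- tabulate(sff_read$flow_of_base + 1L, nbins = nf)
  hri <- is_hri_flow(v100, hc, include_3mers)
  is_call <- hc >= 1L & hc <= (2L + include_3mers)
  chri <- cumsum(hri & is_call)
  ccall <- cumsum(is_call)
  frac <- ifelse(ccall > 0L, chri / ccall, 0)
  ok <- which(frac <= max_frac)
  k <- if (length(ok)) max(ok) else 0L
  # removing trailing flows one at a time stops at the longest prefix
  # satisfying the rule; flows after the last acceptable prefix are cut
  nb <- if (k > 0L) sum(hc[seq_len(k)]) else 0L
  list(clip = c(1L, nb), flows_retained = k, discarded = nb < 4L)
}

#' Apply the trimming treatments to a set of reads
#'
#' Computes, per read, the retained base interval under each treatment:
#' `AT` (analysis trim to the kit's nominal length), `AT+QT` (plus the
#' SFF quality/adapter clip, or the windowed Q9/30 bp fallback),
#' `AT+QT+HRI` (plus 1/2-mer HRI flow trimming) and `AT+QT+HRI3` (HRI
#' including 3-mers). Reads shorter than 4 bases after clipping are
#' discarded.
#'
#' @param sff Output of [read_sff()].
#' @param kit Kit label (sets the analysis-trim cap).
#' @param treatments Character vector of treatments to compute.
#' @return `data.table`: name, treatment, clip_start, clip_end (1-based
#'   inclusive), retained (bases), discarded.
#' @export
trim_reads <- function(sff, kit,
                       treatments = c("AT", "AT+QT", "AT+QT+HRI",
                                      "AT+QT+HRI3")) {
  cap <- kit_nominal_length(kit)
  out <- vector("list", length(sff$reads))
  for (i in seq_along(sff$reads)) {
    rd <- sff$reads[[i]]
    nb <- nchar(rd$bases)
    ends <- c(AT = min(nb, cap))
    if (any(treatments != "AT")) {
      qc <- effective_clip(rd)
      ends["AT+QT"] <- min(ends[["AT"]], qc[2])
      if ("AT+QT+HRI" %in% treatments)
        ends["AT+QT+HRI"] <- min(ends[["AT+QT"]],
                                 hri_trim(rd, FALSE)$clip[2])
      if ("AT+QT+HRI3" %in% treatments)
        ends["AT+QT+HRI3"] <- min(ends[["AT+QT"]],
                                  hri_trim(rd, TRUE)$clip[2])
    }
    ends <- ends[treatments]
    out[[i]] <- data.table::data.table(
      name = rd$name, treatment = treatments, clip_start = 1L,
      clip_end = as.integer(ends), retained = pmax(as.integer(ends), 0L))
  }
  dt <- data.table::rbindlist(out)
  dt[, discarded := retained < 4L]
  dt[]
}

#' Dataset metrics per trimming treatment
#'
#' The summary reported per kit and treatment: insertion/deletion rates
#' (alignment-length denominator, bases 10 and greater within the retained
#' interval), read-length percentiles, percentage of data (bases)
#' retained, percentage of error-free reads, and errors-per-read
#' percentiles.
#'
#' @param trims Output of [trim_reads()].
#' @param columns Bound column table from [profile_run()] (untrimmed; the
#'   per-treatment windows are applied here).
#' @param min_pos Error-counting window start (default 10).
#' @return `data.table`, one row per treatment.
#' @export
kit_metrics <- function(trims, columns, min_pos = 10L) {
  out <- vector("list", length(unique(trims$treatment)))
  i <- 0L
  all_bases <- trims[, .(tot = sum(ifelse(discarded, 0L, retained))),
                     by = treatment]
  base_at <- all_bases$tot[all_bases$treatment == "AT"]
  if (!length(base_at)) base_at <- max(all_bases$tot)
  for (tr in unique(trims$treatment)) {
    i <- i + 1L
    tt <- trims[treatment == tr & discarded == FALSE]
    cols <- merge(columns, tt[, .(name, clip_end)], by = "name")
    cols <- cols[read_pos >= min_pos & read_pos <= clip_end]
    denom <- nrow(cols)
    per_read <- cols[, .(errs = sum(kind != "match")), by = name]
    # reads retained but with no columns in window count as error-free
    n_reads <- nrow(tt)
    errs_all <- c(per_read$errs, rep(0L, max(0L, n_reads - nrow(per_read))))
    qt <- function(x, p) unname(stats::quantile(x, p, type = 1))
    out[[i]] <- data.table::data.table(
      treatment = tr,
      ins_rate = sum(cols$kind == "ins") / denom,
      del_rate = sum(cols$kind == "del") / denom,
      len_p25 = qt(tt$retained, 0.25),
      len_p50 = qt(tt$retained, 0.50),
      len_p75 = qt(tt$retained, 0.75),
      pct_data_retained = 100 * sum(tt$retained) / base_at,
      pct_error_free = 100 * mean(errs_all == 0L),
      errs_p50 = qt(errs_all, 0.50),
      errs_p75 = qt(errs_all, 0.75),
      errs_p99 = qt(errs_all, 0.99),
      n_reads = n_reads)
  }
  data.table::rbindlist(out)
}
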