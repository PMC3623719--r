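#' Find exact repeats in a genome and return them as a mask
#'
#' Every maximal exact repeated substring of length >= `min_len` (both
#' copies, forward strand) is covered by the returned mask, and no position
#' outside such repeats is masked. Uses the fact that a position lies in a
#' repeat of length >= k exactly when some k-mer covering it occurs more
#' than once, so duplicated k-mer start positions expanded by k tile the
#' repeats precisely.
#'
#' @param genome Reference sequence string.
#' @param min_len Minimum repeat length (default 30, the conventional
#'   perfect-match repeat masking threshold).
#' @param contig Contig name for the mask.
#' @return A [mask_set].
#' @export
find_exact_repeats <- function(genome, min_len = 30L, contig = "sim_contig") {
  stopifnot(min_len >= 2)
  L <- nchar(genome)
  if (L < min_len) return(mask_set())
  starts <- seq_len(L - min_len + 1L)
  kmers <- substring(genome, starts, starts + min_len - 1L)
  dup <- duplicated(kmers) | duplicated(kmers, fromLast = TRUE)
  if (!any(dup)) return(mask_set())
  ir <- IRanges::reduce(IRanges::IRanges(starts[dup],
                                         starts[dup] + min_len - 1L))
  mask_set(rep(contig, length(ir)), IRanges::start(ir),
           IRanges::end(ir) + 1L)
}

#' Classify alignment columns of one read
#'
#' Splits a CIGAR alignment into per-column events: CIGAR `M` columns are
#' separated into match and substitution by base comparison (aligners
#' report both as `M`), insertions carry a read base only, deletions a
#' reference base only. Read positions are physical (1-based from the
#' read's 5' end as sequenced), so reverse-strand positions are flipped;
#' a deletion is positioned at the read base immediately 5' of the gap.
#'
#' @param read_seq Read sequence as aligned (SAM SEQ: reverse-complemented
#'   for minus-strand records).
#' @param ref_segment Reference sequence covered by the alignment (forward
#'   genome strand), length equal to the reference span of the CIGAR.
#' @param cigar CIGAR string.
#' @param strand "+" or "-".
#' @param ref_start 1-based genome coordinate of the first reference base.
#' @return `data.table` with one row per M/I/D column: kind ("match",
#'   "sub", "ins", "del"), read_pos (physical; for deletions the 5' flank),
#'   ref_pos (genome coordinate; NA for insertions), ref_anchor (for
#'   insertions, the genome base 5' of the junction on the forward strand),
#'   read_base, ref_base, aln_idx (column index in alignment order).
#' @export
classify_alignment <- function(read_seq, ref_segment, cigar, strand = "+",
                               ref_start = 1L) {
  o <- cigar_ops(cigar)[[1]]
  if (any(o$op %in% c("H", "P")))
    stop("hard-clipped/padded CIGARs are not supported")
  op <- rep.int(o$op, o$len)
  op[op %in% c("=", "X")] <- "M"
  consumes_read <- op %in% c("M", "I", "S")
  consumes_ref <- op %in% c("M", "D", "N")
  seq_pos <- ifelse(consumes_read, cumsum(consumes_read), NA_integer_)
  ref_off <- ifelse(consumes_ref, cumsum(consumes_ref), NA_integer_)
  n_read <- sum(consumes_read)
  if (n_read != nchar(read_seq))
    stop("CIGAR-implied read length (", n_read,
         ") disagrees with sequence length (", nchar(read_seq), ")")
  if (sum(consumes_ref) != nchar(ref_segment))
    stop("CIGAR reference span disagrees with ref_segment length")
  keep <- op %in% c("M", "I", "D")
  op <- op[keep]; seq_pos <- seq_pos[keep]; ref_off <- ref_off[keep]
  rchars <- strsplit(read_seq, "")[[1]]
  gchars <- strsplit(ref_segment, "")[[1]]
  read_base <- ifelse(is.na(seq_pos), NA_character_, rchars[seq_pos])
  ref_base <- ifelse(is.na(ref_off), NA_character_, gchars[ref_off])
  kind <- character(length(op))
  kind[op == "I"] <- "ins"
  kind[op == "D"] <- "del"
  kind[op == "M"] <- ifelse(read_base[op == "M"] == ref_base[op == "M"],
                            "match", "sub")
  # physical read position; deletions take the physical 5'-flank base
  phys <- if (strand == "+") seq_pos else nchar(read_seq) + 1L - seq_pos
  ph <- ifelse(op == "D", NA_integer_, phys)
  flank_aln <- if (strand == "+") nafill_locf(ph) else rev(nafill_locf(rev(ph)))
  other <- if (strand == "+") rev(nafill_locf(rev(ph))) else nafill_locf(ph)
  flank_aln[is.na(flank_aln)] <- other[is.na(flank_aln)]  # no 5' flank:
  read_pos <- ifelse(op == "D", flank_aln, phys)          # use the 3' one
  # insertion junction: the forward-strand genome base 5' of the insert
  anchor <- nafill_locf(ifelse(op == "I", NA_integer_, ref_off))
  anchor[is.na(anchor)] <- 0L            # insertion before any ref base
  data.table::data.table(
    kind = kind, read_pos = as.integer(read_pos),
    ref_pos = ref_start - 1L + ref_off,
    ref_anchor = ifelse(op == "I", ref_start - 1L + anchor, NA_integer_),
    read_base = read_base, ref_base = ref_base,
    aln_idx = seq_along(op))
}

nafill_locf <- function(x) {
  i <- cumsum(!is.na(x))
  out <- x[!is.na(x)][pmax(i, 1L)]
  out[i == 0L] <- NA
  out
}

#' Restrict alignment columns to the analysis window
#'
#' Keeps columns at physical base positions >= 10 (avoiding 5'
#' misalignments and key-adjacent homopolymers) and within the kit's
#' nominal length: 100 bp for OT100, 200 bp for M200/OT200. A deletion is
#' retained only when both flanking read bases lie inside the window.
#'
#' @param columns A column table from [classify_alignment()].
#' @param kit Kit label.
#' @param min_pos Lower bound on base position (default 10).
#' @return The filtered column table.
#' @export
analysis_trim <- function(columns, kit, min_pos = 10L) {
  cap <- kit_nominal_length(kit)
  keep <- ifelse(columns$kind == "del",
                 columns$read_pos >= min_pos & columns$read_pos + 1L <= cap,
                 columns$read_pos >= min_pos & columns$read_pos <= cap)
  columns[keep]
}

#' Project alignment columns of one read onto its flows
#'
#' Turns base-level alignment columns into per-flow observations carrying
#' the reference (true) and called homopolymer lengths. Read bases map to
#' flows through the SFF per-base flow index; a deleted reference base is
#' attributed to the flow that should have incorporated it: the current
#' flow when its nucleotide matches, otherwise the first later flow
#' dispensing that nucleotide (bounded by the next aligned base's flow —
#' an alignment implying a nucleotide-order violation is flagged and
#' excluded). Flows overlapping substitution columns are flagged so they
#' can be excluded from homopolymer statistics; flows only partially inside
#' the aligned region are dropped and counted.
#'
#' @param sff_read One read record from [read_sff()] (fields `values`,
#'   `flow_of_base`, and per-flow called lengths derived from them).
#' @param columns Column table from [classify_alignment()] for that read.
#' @param order The [flow_order].
#' @param strand "+" or "-".
#' @return `data.table` with one row per projectable flow: flow, h_true,
#'   h_called, sub (flag), y, cycle, pic; attributes `n_unprojectable` and
#'   `n_partial` count excluded columns/flows.
#' @export
project_to_flows <- function(sff_read, columns, order, strand = "+") {
  P <- order$period
  dtab <- flow_distance_table(order)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n_flows <- length(sff_read$values)
  hp <- tabulate(sff_read$flow_of_base + 1L, nbins = n_flows)
  cols <- columns
  if (strand == "-") cols <- cols[rev(seq_len(nrow(cols)))]  # physical order
  has_base <- cols$kind != "del"
  flow_col <- rep(NA_integer_, nrow(cols))
  flow_col[has_base] <- sff_read$flow_of_base[cols$read_pos[has_base]]
  prev_flow <- nafill_locf(flow_col)
  next_flow <- rev(nafill_locf(rev(flow_col)))
  n_unproj <- 0L
  didx <- which(!has_base)
  if (length(didx)) {
    dbase <- cols$ref_base[didx]
    if (strand == "-") dbase <- unname(comp[dbase])
    # consecutive deletions chain through the running flow pointer
    runs <- split(seq_along(didx), cumsum(c(1L, diff(didx) != 1L)))
    for (rn in runs) {
      cf <- prev_flow[didx[rn[1]]]
      bound <- next_flow[didx[rn[length(rn)]]]
      if (is.na(cf)) { n_unproj <- n_unproj + length(rn); next }
      ok <- TRUE
      for (j in rn) {
        b <- dbase[j]
        if (order$nucleotides[cf %% P + 1L] != b)
          cf <- cf + 1L + dtab[(cf + 1L) %% P + 1L, b]
        if (!is.na(bound) && cf > bound) { ok <- FALSE; break }
        flow_col[didx[j]] <- cf
      }
      if (!ok) {
        n_unproj <- n_unproj + length(rn)
        flow_col[didx[rn]] <- NA_integer_
      }
    }
  }
  aligned <- cols[!is.na(flow_col)]
  aflow <- flow_col[!is.na(flow_col)]
  if (!nrow(aligned))
    return(empty_flow_obs(n_unproj, 0L))
  fmin <- min(aflow); fmax <- max(aflow)
  f_range <- fmin:fmax
  h_true <- tabulate(aflow[aligned$kind != "ins"] - fmin + 1L,
                     nbins = length(f_range))
  n_aligned_base <- tabulate(flow_col[has_base & !is.na(flow_col)] -
                               fmin + 1L, nbins = length(f_range))
  sub_flow <- tabulate(aflow[aligned$kind == "sub"] - fmin + 1L,
                       nbins = length(f_range)) > 0L
  h_called <- hp[f_range + 1L]
  # a flow is partial when some of its called bases fall outside the
  # aligned region (soft-clipped or unprojectable); dropped and counted
  partial <- h_called != n_aligned_base
  obs <- data.table::data.table(
    flow = f_range, h_true = as.integer(h_true),
    h_called = as.integer(h_called), sub = sub_flow,
    y = sff_read$values[f_range + 1L],
    cycle = f_range %/% P, pic = f_range %% P)[!partial]
  attr(obs, "n_unprojectable") <- n_unproj
  attr(obs, "n_partial") <- sum(partial)
  obs
}

empty_flow_obs <- function(n_unproj = 0L, n_partial = 0L) {
  obs <- data.table::data.table(
    flow = integer(0), h_true = integer(0), h_called = integer(0),
    sub = logical(0), y = numeric(0), cycle = integer(0), pic = integer(0))
  attr(obs, "n_unprojectable") <- n_unproj
  attr(obs, "n_partial") <- n_partial
  obs
}

#' Profile a run: classify every alignment and project it onto flows
#'
#' The per-run driver tying the format layer to the analyses: for every
#' mapped SAM record it extracts the reference segment, classifies the
#' alignment columns, optionally applies the analysis trim, and projects
#' the columns onto flows through the SFF read.
#'
#' @param sff Output of [read_sff()] (or the `sff` element of a
#'   [simulate_run()] object).
#' @param sam Output of [read_sam()] (or a `data.table` of SAM records).
#' @param genome Reference sequence string.
#' @param kit Kit label for [analysis_trim()]; `NULL` skips trimming.
#' @param mask Optional [mask_set]; columns whose reference position (or
#'   insertion anchor) is masked are dropped before flow projection.
#' @param contig Contig name of `genome`.
#' @return List with `columns` (all column tables bound, plus `name` and
#'   `strand`), `observations` (all flow observations bound, plus `name`
#'   and `strand`), and counts `n_unprojectable`, `n_partial`.
#' @export
profile_run <- function(sff, sam, genome, kit = NULL, mask = NULL,
                        contig = "sim_contig") {
  records <- if (is.data.frame(sam)) data.table::as.data.table(sam)
             else sam$records
  records <- records[records$flag != 4L & records$cigar != "*", ]
  if (!"strand" %in% names(records))
    records[, strand := ifelse(bitwAnd(flag, 16L) != 0L, "-", "+")]
  if (!"ref_width" %in% names(records))
    records[, ref_width := vapply(cigar_ops(cigar), function(o)
      sum(o$len[o$op %in% c("M", "D", "N", "=", "X")]), integer(1))]
  sff_by_name <- stats::setNames(sff$reads,
                                 vapply(sff$reads, `[[`, character(1), "name"))
  mbits <- if (!is.null(mask)) mask_bits(mask, contig, nchar(genome))
  col_list <- vector("list", nrow(records))
  obs_list <- vector("list", nrow(records))
  n_unproj <- 0L; n_partial <- 0L
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    ref_seg <- substr(genome, rec$pos, rec$pos + rec$ref_width - 1L)
    cols <- classify_alignment(rec$seq, ref_seg, rec$cigar, rec$strand,
                               ref_start = rec$pos)
    if (!is.null(kit)) cols <- analysis_trim(cols, kit)
    if (!is.null(mbits)) {
      cpos <- ifelse(is.na(cols$ref_pos), cols$ref_anchor, cols$ref_pos)
      cols <- cols[!(cpos >= 1L & mbits[pmax(cpos, 1L)])]
    }
    if (!nrow(cols)) next
    obs <- project_to_flows(sff_by_name[[rec$qname]], cols, sff$order,
                            rec$strand)
    n_unproj <- n_unproj + attr(obs, "n_unprojectable")
    n_partial <- n_partial + attr(obs, "n_partial")
    cols[, name := rec$qname]; cols[, strand := rec$strand]
    if (nrow(obs)) { obs[, name := rec$qname]; obs[, strand := rec$strand] }
    col_list[[i]] <- cols
    obs_list[[i]] <- obs
  }
  list(columns = data.table::rbindlist(col_list),
       observations = data.table::rbindlist(obs_list),
       n_unprojectable = n_unproj, n_partial = n_partial)
}

#' Base-level error rates from alignment columns
#'
#' The denominator is the alignment length (number of columns), so deletion
#' errors contribute to both numerator and denominator. Per-position curves
#' use the physical read base position (deletions at their 5' flank).
#'
#' @param columns Bound column table (e.g. from [profile_run()]).
#' @return List with `rates` (`data.table`: type, n, denom, rate) and
#'   `by_position` (`data.table`: read_pos, type, n, denom, rate).
#' @export
base_error_rates <- function(columns) {
  if (!nrow(columns)) stop("no alignment columns")
  denom <- nrow(columns)
  kinds <- c("sub", "ins", "del")
  rates <- data.table::data.table(
    type = kinds,
    n = vapply(kinds, function(k) sum(columns$kind == k), integer(1)),
    denom = denom)
  rates[, rate := n / denom]
  bp <- columns[, .(denom = .N,
                    sub = sum(kind == "sub"), ins = sum(kind == "ins"),
                    del = sum(kind == "del")), by = read_pos]
  by_pos <- data.table::melt(bp, id.vars = c("read_pos", "denom"),
                             variable.name = "type", value.name = "n",
                             variable.factor = FALSE)
  by_pos[, rate := n / denom]
  data.table::setorder(by_pos, read_pos, type)
  list(rates = rates[], by_position = by_pos[])
}

#' Flow-level error rates and homopolymer accuracy
#'
#' Rates use the flow-call denominator: the number of flows which were, or
#' should have been, an h-mer. Substitution-overlapping flows are excluded.
#'
#' @param observations Bound flow-observation table from [profile_run()].
#' @return List of `data.table`s: `by_flow` (flow, n, error rate),
#'   `by_h` (h_true, n, accuracy, over_rate, under_rate), `by_pic`
#'   (pic, n, ins_rate, del_rate), and `zero_by_pic_cycle` (pic, cycle, n,
#'   overcall_rate for h_true = 0).
#' @export
flow_error_rates <- function(observations) {
  obs <- observations[observations$sub == FALSE]
  by_flow <- obs[, .(n = .N, rate = mean(h_called != h_true)), by = flow]
  by_h <- obs[, .(n = .N, accuracy = mean(h_called == h_true),
                  over_rate = mean(h_called > h_true),
                  under_rate = mean(h_called < h_true)), by = h_true]
  by_pic <- obs[, .(n = .N, ins_rate = mean(h_called > h_true),
                    del_rate = mean(h_called < h_true)), by = pic]
  zero <- obs[h_true == 0L,
              .(n = .N, overcall_rate = mean(h_called >= 1L)),
              by = .(pic, cycle)]
  data.table::setorder(by_flow, flow)
  data.table::setorder(by_h, h_true)
  data.table::setorder(by_pic, pic)
  data.table::setorder(zero, pic, cycle)
  list(by_flow = by_flow[], by_h = by_h[], by_pic = by_pic[],
       zero_by_pic_cycle = zero[])
}

#' Substitution spectrum
#'
#' Breakdown of substitution type (reference base to read base, 12 cells)
#' as a proportion of all substitutions.
#' @param columns Bound column table.
#' @return `data.table` with ref_base, read_base, n, proportion (summing
#'   to 1); zero rows when there are no substitutions.
#' @export
substitution_spectrum <- function(columns) {
  subs <- columns[columns$kind == "sub"]
  grid <- data.table::CJ(ref_base = c("A", "C", "G", "T"),
                         read_base = c("A", "C", "G", "T"))
  grid <- grid[ref_base != read_base]
  if (!nrow(subs)) {
    grid[, `:=`(n = 0L, proportion = numeric(1))]
    return(grid[])
  }
  cnt <- subs[, .(n = .N), by = .(ref_base, read_base)]
  out <- merge(grid, cnt, by = c("ref_base", "read_base"), all.x = TRUE)
  out[is.na(n), n := 0L]
  out[, proportion := n / sum(n)]
  out[]
}

#' Chi-square test of read start-position uniformity
#'
#' Bins exclude the first and last 120 bp of the reference and any masked
#' intervals; also reports how many (start, strand) pairs are shared by
#' multiple reads (replicate-bias diagnostic).
#'
#' @param starts `data.table`/data.frame with columns `start` (1-based
#'   5'-aligned genome position) and `strand`.
#' @param genome_len Reference length.
#' @param mask Optional [mask_set].
#' @param n_bins Number of bins (default 20).
#' @param end_exclusion Bases excluded at each reference end (default 120).
#' @param contig Contig name for mask lookup.
#' @return List with `statistic`, `df`, `p_value`, `n_used`, and
#'   `duplicate_starts` (`data.table`: n_reads_sharing, n_sites).
#' @export
start_uniformity <- function(starts, genome_len, mask = NULL, n_bins = 20L,
                             end_exclusion = 120L, contig = "sim_contig") {
  if (genome_len < 2L * end_exclusion) stop("reference shorter than 240 bp")
  if (nrow(starts) < 100L) stop("need at least 100 mapped reads")
  allowed <- rep(TRUE, genome_len)
  allowed[seq_len(end_exclusion)] <- FALSE
  allowed[(genome_len - end_exclusion + 1L):genome_len] <- FALSE
  if (!is.null(mask)) allowed[mask_bits(mask, contig, genome_len)] <- FALSE
  use <- starts$start >= 1L & starts$start <= genome_len &
    allowed[starts$start]
  s <- starts$start[use]
  pos_allowed <- which(allowed)
  bin_of <- cut(pos_allowed, breaks = n_bins, labels = FALSE)
  expected_w <- tabulate(bin_of, n_bins)
  obs <- tabulate(bin_of[match(s, pos_allowed)], n_bins)
  ct <- stats::chisq.test(obs, p = expected_w / sum(expected_w))
  dup <- data.table::as.data.table(starts[use, c("start", "strand")])
  dup <- dup[, .(n_reads = .N), by = .(start, strand)]
  dup_hist <- dup[, .(n_sites = .N), by = .(n_reads_sharing = n_reads)]
  data.table::setorder(dup_hist, n_reads_sharing)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), n_used = length(s),
       duplicate_starts = dup_hist[])
}

#' Flag unexpectedly long reads
#'
#' Reads longer than the kit's nominal length times `threshold_factor`
#' (default 1.25) carry roughly double the mean error rate and are flagged
#' for removal.
#' @param read_lengths Integer vector of read lengths.
#' @param kit Kit label.
#' @param threshold_factor Multiplier of the nominal kit length.
#' @return Logical vector, TRUE for flagged reads.
#' @export
flag_overlong_reads <- function(read_lengths, kit, threshold_factor = 1.25) {
  read_lengths > kit_nominal_length(kit) * threshold_factor
}
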