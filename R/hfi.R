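#' Build per-site pileups of read/reference differences
#'
#' Aggregates alignment columns into per-reference-position counts of
#' substitutions, insertions and deletions split by read strand, together
#' with per-strand coverage from the alignment spans. An indel spanning
#' several reference bases is counted once at its 5'-most base; several
#' bases inserted at the same junction count once, at the junction's left
#' base. Insertion site coverage is handled downstream (adjacent-maximum
#' rule, see [site_binomial_tests()]).
#'
#' @param columns Bound column table from [profile_run()] (with `name` and
#'   `strand`).
#' @param sam_records Mapped SAM records (`data.table` with pos, ref_width,
#'   strand).
#' @param genome_len Reference length.
#' @param genome Optional reference string; when given, each site carries
#'   its reference homopolymer length.
#' @return `data.table` with one row per covered position: pos, h,
#'   cov_fwd, cov_rev, sub_fwd, sub_rev, ins_fwd, ins_rev, del_fwd,
#'   del_rev.
#' @export
build_site_pileups <- function(columns, sam_records, genome_len,
                               genome = NULL) {
  cov_strand <- function(s) {
    recs <- sam_records[sam_records$strand == s, ]
    if (!nrow(recs)) return(integer(genome_len))
    as.integer(IRanges::coverage(
      IRanges::IRanges(recs$pos, width = recs$ref_width),
      width = genome_len))
  }
  cov_f <- cov_strand("+")
  cov_r <- cov_strand("-")
  count_at <- function(pos) tabulate(pos, nbins = genome_len)
  subs <- columns[columns$kind == "sub"]
  # one event per (read, run of adjacent deleted bases), at the 5'-most base
  dels <- columns[columns$kind == "del"]
  if (nrow(dels)) {
    data.table::setorder(dels, name, aln_idx)
    dels[, grp := cumsum(c(1L, diff(aln_idx) != 1L)), by = name]
    dels <- dels[, .(ref_pos = min(ref_pos), strand = strand[1]),
                 by = .(name, grp)]
  }
  ins <- columns[columns$kind == "ins"]
  if (nrow(ins))
    ins <- ins[, .(n = .N), by = .(name, strand, ref_anchor)]
  dt <- data.table::data.table(
    pos = seq_len(genome_len),
    cov_fwd = cov_f, cov_rev = cov_r,
    sub_fwd = count_at(subs$ref_pos[subs$strand == "+"]),
    sub_rev = count_at(subs$ref_pos[subs$strand == "-"]),
    ins_fwd = if (nrow(ins)) count_at(ins$ref_anchor[ins$strand == "+"])
              else integer(genome_len),
    ins_rev = if (nrow(ins)) count_at(ins$ref_anchor[ins$strand == "-"])
              else integer(genome_len),
    del_fwd = if (nrow(dels)) count_at(dels$ref_pos[dels$strand == "+"])
              else integer(genome_len),
    del_rev = if (nrow(dels)) count_at(dels$ref_pos[dels$strand == "-"])
              else integer(genome_len))
  if (!is.null(genome)) {
    r <- rle(strsplit(toupper(genome), "")[[1]])
    dt[, h := rep(r$lengths, r$lengths)]
  } else dt[, h := NA_integer_]
  dt[cov_fwd + cov_rev > 0L]
}

#' Estimate null error rates from pileups
#'
#' The substitution null is the mean substitution rate; the indel null is
#' parameterised on the reference homopolymer length (error rates grow
#' with h). Lengths with fewer than `min_cov` covering observations are
#' pooled with the largest well-observed length.
#'
#' @param pileups From [build_site_pileups()] or
#'   [simulate_site_pileups()].
#' @param min_cov Minimum total coverage for a per-h rate (default 1000).
#' @return List with `sub_rate` (scalar) and `indel_rate` (`data.table`:
#'   h, rate, n; attribute `pooled_above` gives the last unpooled h).
#' @export
estimate_null_rates <- function(pileups, min_cov = 1000) {
  cov <- pileups$cov_fwd + pileups$cov_rev
  if (sum(cov) < 1e4)
    stop("too little data to estimate null rates (need >= 10^4 columns)")
  sub_rate <- sum(pileups$sub_fwd + pileups$sub_rev) / sum(cov)
  ind <- pileups[, .(
    n = sum(cov_fwd + cov_rev),
    x = sum(ins_fwd + ins_rev + del_fwd + del_rev)), by = h]
  data.table::setorder(ind, h)
  ok <- ind$n >= min_cov
  if (!any(ok)) stop("no homopolymer length has enough coverage")
  h_max <- max(ind$h[ok])
  pool <- ind$h > h_max
  if (any(pool)) {
    warning("pooling indel null rates for h > ", h_max,
            " (sparse long homopolymers)")
    pooled <- ind[pool | h == h_max, .(h = h_max, n = sum(n), x = sum(x))]
    ind <- rbind(ind[h < h_max], pooled)
  }
  ind[, rate := x / n]
  list(sub_rate = sub_rate, indel_rate = ind[, .(h, rate, n)],
       h_cap = h_max)
}

indel_null_rate <- function(null_rates, h) {
  tab <- null_rates$indel_rate
  hh <- pmin(h, null_rates$h_cap)
  tab$rate[match(hh, tab$h)]
}

#' Exact binomial upper-tail tests at every site
#'
#' Models the observed number of differences X at each reference position
#' as Binomial(coverage, null rate) and computes the exact upper-tail
#' p-value P(X >= x). For single-base insertions the coverage is the
#' maximum coverage of the bases immediately adjacent to the junction.
#' Holm-corrected p-values are computed per type (one family per type per
#' run), significance at adjusted p < 0.05.
#'
#' @param pileups From [build_site_pileups()].
#' @param null_rates From [estimate_null_rates()].
#' @param alpha Family-wise significance level (default 0.05).
#' @return `data.table` with one row per site x type having x > 0: pos, h,
#'   type, x, n, p_raw, p_holm, significant. The Holm family for each type
#'   is every covered site, not only those with observed differences.
#' @export
site_binomial_tests <- function(pileups, null_rates, alpha = 0.05) {
  cov <- pileups$cov_fwd + pileups$cov_rev
  # adjacent-max coverage for insertion junctions: bases pos and pos + 1
  cov_by_pos <- stats::setNames(cov, pileups$pos)
  cov_next <- cov_by_pos[as.character(pileups$pos + 1L)]
  cov_ins <- pmax(cov, cov_next, na.rm = TRUE)
  per_type <- function(type, x, n, p0) {
    p_raw <- stats::pbinom(x - 1L, n, p0, lower.tail = FALSE)
    p_holm <- stats::p.adjust(p_raw, method = "holm")
    data.table::data.table(pos = pileups$pos, h = pileups$h, type = type,
                           x = x, n = n, p_raw = p_raw, p_holm = p_holm,
                           significant = p_holm < alpha)
  }
  p_ind <- indel_null_rate(null_rates, pileups$h)
  out <- rbind(
    per_type("sub", pileups$sub_fwd + pileups$sub_rev, cov,
             null_rates$sub_rate),
    per_type("ins", pileups$ins_fwd + pileups$ins_rev, cov_ins, p_ind),
    per_type("del", pileups$del_fwd + pileups$del_rev, cov, p_ind))
  out[x > 0L]
}

#' Holm step-down adjustment
#'
#' Thin wrapper over [stats::p.adjust()] (method "holm"), kept as a named
#' operation because every site-level test in the pipeline is corrected
#' with it.
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")

#' Fisher exact tests of indel strand asymmetry
#'
#' At each significant indel site with reads aligned in both orientations,
#' the 2x2 table (strand x indel presence/absence) is tested with the
#' two-sided Fisher exact test; p-values are Holm-adjusted over the family
#' of all testable sites in the run. Single-strand sites are marked
#' untestable and excluded from the family.
#'
#' @param sites Significant indel rows from [site_binomial_tests()].
#' @param pileups From [build_site_pileups()].
#' @param alpha Family-wise level (default 0.05).
#' @return `data.table`: pos, type, x_fwd, n_fwd, x_rev, n_rev, testable,
#'   asym_p_raw, asym_p_holm, asym_significant.
#' @export
strand_asymmetry_tests <- function(sites, pileups, alpha = 0.05) {
  ind <- sites[sites$type %in% c("ins", "del") & sites$significant, ]
  if (!nrow(ind))
    return(data.table::data.table(
      pos = integer(0), type = character(0), x_fwd = integer(0),
      n_fwd = integer(0), x_rev = integer(0), n_rev = integer(0),
      testable = logical(0), asym_p_raw = numeric(0),
      asym_p_holm = numeric(0), asym_significant = logical(0)))
  pl <- pileups[match(ind$pos, pileups$pos)]
  x_f <- ifelse(ind$type == "ins", pl$ins_fwd, pl$del_fwd)
  x_r <- ifelse(ind$type == "ins", pl$ins_rev, pl$del_rev)
  n_f <- pl$cov_fwd
  n_r <- pl$cov_rev
  testable <- n_f >= 1L & n_r >= 1L
  p_raw <- rep(NA_real_, nrow(ind))
  for (i in which(testable)) {
    tab <- matrix(c(min(x_f[i], n_f[i]), n_f[i] - min(x_f[i], n_f[i]),
                    min(x_r[i], n_r[i]), n_r[i] - min(x_r[i], n_r[i])),
                  nrow = 2, byrow = TRUE)
    p_raw[i] <- stats::fisher.test(tab)$p.value
  }
  p_holm <- rep(NA_real_, nrow(ind))
  p_holm[testable] <- holm_adjust(p_raw[testable])
  data.table::data.table(
    pos = ind$pos, type = ind$type, x_fwd = x_f, n_fwd = n_f,
    x_rev = x_r, n_rev = n_r, testable = testable,
    asym_p_raw = p_raw, asym_p_holm = p_holm,
    asym_significant = !is.na(p_holm) & p_holm < alpha)
}

#' Intersect HFI site sets across runs
#'
#' Sites are keyed by (position, type). Reports pairwise overlap counts,
#' the k-way (all-run) intersection, and each run's fraction of sites seen
#' in no other run.
#'
#' @param site_sets Named list of `data.table`s with columns pos, type
#'   (significant sites per run, same reference).
#' @return List with `pairwise` (matrix of shared-site counts), `shared_all`
#'   (count in every run), `unique_fraction` (named vector), `n_sites`.
#' @export
intersect_sites <- function(site_sets) {
  if (length(site_sets) < 2L) stop("need >= 2 runs to intersect")
  keys <- lapply(site_sets, function(s) paste(s$pos, s$type))
  n <- length(keys)
  runs <- names(keys)
  if (is.null(runs)) runs <- paste0("run", seq_len(n))
  pw <- matrix(0L, n, n, dimnames = list(runs, runs))
  for (i in seq_len(n)) for (j in seq_len(n))
    pw[i, j] <- length(intersect(keys[[i]], keys[[j]]))
  occur <- table(unlist(lapply(keys, unique)))
  uniq_frac <- vapply(seq_len(n), function(i) {
    k <- unique(keys[[i]])
    if (!length(k)) return(NA_real_)
    mean(occur[k] == 1L)
  }, numeric(1))
  names(uniq_frac) <- runs
  list(pairwise = pw,
       shared_all = sum(occur == n),
       unique_fraction = uniq_frac,
       n_sites = vapply(keys, function(k) length(unique(k)), integer(1)))
}

#' Mask significant HFI sites
#'
#' One 1 bp interval per site; insertion sites mask both bases flanking the
#' junction.
#' @param sites Significant rows from [site_binomial_tests()].
#' @param contig Contig name.
#' @return A [mask_set].
#' @export
hfi_mask <- function(sites, contig = "sim_contig") {
  sig <- sites[sites$significant, ]
  if (!nrow(sig)) return(mask_set())
  start <- sig$pos
  end <- ifelse(sig$type == "ins", sig$pos + 2L, sig$pos + 1L)
  mask_set(rep(contig, nrow(sig)), start, end)
}
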