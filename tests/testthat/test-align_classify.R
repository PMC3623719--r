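# offset-scan oracle: positions covered by any exact repeat of length >= k
repeat_cover_oracle <- function(genome, k) {
  chars <- strsplit(genome, "")[[1]]
  L <- length(chars)
  covered <- logical(L)
  for (d in seq_len(L - 1)) {
    eq <- chars[seq_len(L - d)] == chars[seq_len(L - d) + d]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= k)) {
      covered[starts[j]:ends[j]] <- TRUE          # first copy
      covered[(starts[j] + d):(ends[j] + d)] <- TRUE  # second copy
    }
  }
  covered
}

test_that("exact-repeat masking matches an offset-scan oracle", {
  set.seed(21)
  # planted duplicate: exactly two 40 bp intervals
  core <- random_seq(40)
  g <- paste0(random_seq(200), core, random_seq(150), core, random_seq(100))
  m <- find_exact_repeats(g, 30L, contig = "c")
  expect_identical(mask_bits(m, "c", nchar(g)),
                   repeat_cover_oracle(g, 30L))
  # random short genomes: typically empty at 30, always oracle-equal at 8
  for (i in 1:10) {
    g2 <- random_seq(250)
    expect_identical(mask_bits(find_exact_repeats(g2, 30L, "c"), "c", 250L),
                     repeat_cover_oracle(g2, 30L))
    expect_identical(mask_bits(find_exact_repeats(g2, 8L, "c"), "c", 250L),
                     repeat_cover_oracle(g2, 8L))
  }
  expect_identical(nrow(find_exact_repeats(random_seq(60, seed = 2), 30L)),
                   0L)  # a genome is not its own repeat
})

test_that("alignment columns split M into match and substitution", {
  cols <- classify_alignment("ACGT", "ACGT", "4M", "+")
  expect_identical(cols$kind, rep("match", 4))
  cols <- classify_alignment("ACTT", "ACGT", "4M", "+")
  expect_identical(cols$kind, c("match", "match", "sub", "match"))
  cols <- classify_alignment("ACGT", "ACT", "2M1I1M", "+", ref_start = 11L)
  expect_identical(cols$kind, c("match", "match", "ins", "match"))
  expect_identical(cols$ref_pos, c(11L, 12L, NA_integer_, 13L))
  expect_identical(cols$ref_anchor[3], 12L)
  cols <- classify_alignment("ACT", "ACGT", "2M1D1M", "+")
  expect_identical(cols$kind, c("match", "match", "del", "match"))
  expect_identical(cols$read_pos, c(1L, 2L, 2L, 3L))  # del at 5' flank
  expect_error(classify_alignment("ACGT", "ACGT", "5M", "+"), "disagrees")
  # conservation: columns == alignment length for random CIGARs
  expect_identical(nrow(classify_alignment("ACGTACGT", "ACGTACG",
                                           "3M2I3M1D", "+")), 9L)
})

test_that("reverse-strand columns use physical read coordinates", {
  # read physically TTAC -> aligned as GTAA (revcomp)
  cols <- classify_alignment("GTAA", "GTAA", "4M", "-")
  expect_identical(cols$read_pos, 4:1)
  cols <- classify_alignment("GTA", "GTAA", "3M1D", "-")
  # deletion after aligned pos 3; physical 5' flank is position 1
  expect_identical(cols$read_pos[cols$kind == "del"], 1L)
})

test_that("the analysis trim window drops early and late positions", {
  cols <- data.table::data.table(
    kind = c("match", "match", "match", "del", "ins"),
    read_pos = c(5L, 10L, 150L, 99L, 100L),
    ref_pos = 1:5, ref_anchor = NA_integer_,
    read_base = "A", ref_base = "A", aln_idx = 1:5)
  at <- analysis_trim(cols, "OT100")
  expect_identical(at$read_pos, c(10L, 99L, 100L))  # 5 and 150 dropped
  expect_identical(analysis_trim(cols, "M200")$read_pos,
                   c(10L, 150L, 99L, 100L))
  expect_error(analysis_trim(cols, "KIT9000"))
})

test_that("flow projection reproduces a hand-built over-call", {
  o <- tacg_order()
  rd <- fake_sff_read(c(2.1, 1.0, 0.1, 1.0), o)   # calls TTAG
  expect_identical(rd$bases, "TTAG")
  cols <- classify_alignment("TTAG", "TAG", "1M1I2M", "+")
  obs <- project_to_flows(rd, cols, o, "+")
  expect_identical(obs$h_true, c(1L, 1L, 0L, 1L))
  expect_identical(obs$h_called, c(2L, 1L, 0L, 1L))
  expect_identical(sum(obs$h_called > obs$h_true), 1L)
})

test_that("deleted runs are attributed to the flow that should have fired", {
  o <- tacg_order()
  # ref TACCG, read TACG: the CC 2-mer under-called to C at flow 1 (C)
  rd <- fake_sff_read(c(1.0, 1.0, 1.45, 1.0), o)  # calls TACG, C flow 1.45
  cols <- classify_alignment("TACG", "TACCG", "3M1D1M", "+")
  obs <- project_to_flows(rd, cols, o, "+")
  cc <- obs[obs$flow == 2L]
  expect_identical(cc$h_true, 2L)
  expect_identical(cc$h_called, 1L)
  # ref TACG, read TAG: fully deleted C goes to the C flow (h 1 -> 0)
  rd2 <- fake_sff_read(c(1.0, 1.0, 0.2, 1.0), o)
  cols2 <- classify_alignment("TAG", "TACG", "2M1D1M", "+")
  obs2 <- project_to_flows(rd2, cols2, o, "+")
  expect_identical(obs2[obs2$flow == 2L]$h_true, 1L)
  expect_identical(obs2[obs2$flow == 2L]$h_called, 0L)
})

test_that("projection agrees with the simulator truth ledger end-to-end", {
  hfi <- NULL
  tr <- tiny_run(n_reads = 150L, sub_rate = 2e-3)
  pr <- profile_run(tr$sim$sff, tr$sim$sam, tr$genome, kit = NULL)
  expect_identical(pr$n_unprojectable, 0L)
  expect_identical(pr$n_partial, 0L)
  led <- data.table::setorder(data.table::copy(tr$sim$ledger), name, flow)
  obs <- data.table::setorder(pr$observations, name, flow)
  expect_identical(nrow(obs), nrow(led))
  expect_identical(obs$h_true, led$h_true)
  expect_identical(obs$h_called, led$h_called)
  expect_identical(obs$sub, led$sub)
  # base-level and flow-level error counts reconcile exactly (a
  # substitution occupies an M column, so it changes neither side)
  expect_identical(sum(pr$columns$kind == "ins"),
                   sum(pmax(obs$h_called - obs$h_true, 0L)))
  expect_identical(sum(pr$columns$kind == "del"),
                   sum(pmax(obs$h_true - obs$h_called, 0L)))
})

test_that("base error rates use the alignment-length denominator", {
  cols <- data.table::data.table(
    kind = c(rep("match", 96), "ins", "ins", "del", "sub"),
    read_pos = c(1:96, 50L, 51L, 52L, 53L),
    ref_pos = 1:100, ref_anchor = NA_integer_,
    read_base = "A", ref_base = "A", aln_idx = 1:100)
  r <- base_error_rates(cols)$rates
  expect_identical(r$denom, rep(100L, 3))
  expect_equal(r[r$type == "ins"]$rate, 0.02)
  expect_equal(r[r$type == "del"]$rate, 0.01)
  expect_equal(r[r$type == "sub"]$rate, 0.01)
  expect_error(base_error_rates(cols[0]), "no alignment")
})

test_that("flow error rates give per-h accuracy with correct denominators", {
  obs <- data.table::data.table(
    flow = 0:9, h_true = c(rep(2L, 10)), h_called = c(rep(2L, 9), 3L),
    sub = FALSE, y = 2, cycle = 0L, pic = 0:9)
  fr <- flow_error_rates(obs)
  expect_equal(fr$by_h$accuracy, 0.9)
  expect_equal(fr$by_h$n, 10L)
  obs$h_called <- obs$h_true
  expect_equal(flow_error_rates(obs)$by_h$accuracy, 1)
})

test_that("substitution spectra are proportions over 12 cells", {
  cols <- data.table::data.table(
    kind = c("sub", "sub", "sub", "match"),
    read_pos = 1:4, ref_pos = 1:4, ref_anchor = NA_integer_,
    read_base = c("T", "T", "A", "G"),
    ref_base = c("C", "C", "G", "G"), aln_idx = 1:4)
  sp <- substitution_spectrum(cols)
  expect_identical(nrow(sp), 12L)
  expect_equal(sum(sp$proportion), 1)
  expect_equal(sp[sp$ref_base == "C" & sp$read_base == "T"]$proportion, 2 / 3)
  empty <- substitution_spectrum(cols[kind == "match"])
  expect_identical(sum(empty$n), 0L)
})

test_that("start uniformity detects pileups and respects masks", {
  set.seed(5)
  st <- data.table::data.table(start = rep(500L, 200), strand = "+")
  u <- start_uniformity(st, 5000L, n_bins = 10L)
  expect_lt(u$p_value, 1e-10)
  expect_identical(u$duplicate_starts$n_reads_sharing, 200L)
  expect_error(start_uniformity(st, 200L), "240")
  expect_error(start_uniformity(st[1:50], 5000L), "100")
  m <- mask_set("sim_contig", 121L, 2500L)
  st2 <- data.table::data.table(start = sample(2500:4880, 300, TRUE),
                                strand = "+")
  u2 <- start_uniformity(st2, 5000L, mask = m, n_bins = 8L)
  expect_identical(u2$n_used, sum(st2$start >= 2500))
})

test_that("over-long reads are flagged against the kit nominal length", {
  expect_identical(flag_overlong_reads(c(260L, 100L, 126L, 124L), "OT100"),
                   c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(flag_overlong_reads(c(260L, 240L), "OT200"),
                   c(TRUE, FALSE))
  expect_false(any(flag_overlong_reads(c(900L, 100L), "OT100", Inf)))
})
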