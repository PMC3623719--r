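# brute-force suffix-scan oracle for the HRI trim
hri_oracle <- function(sff_read, include_3mers = FALSE, max_frac = 0.03) {
  v100 <- as.integer(round(sff_read$values * 100))
  nf <- length(v100)
  hc <- tabulate(sff_read$flow_of_base + 1L, nbins = nf)
  in_any <- function(v, rs) any(apply(rs, 1, function(r) v >= r[1] & v <= r[2]))
  for (k in nf:0) {
    if (k == 0L) return(0L)
    idx <- seq_len(k)
    hri <- 0L; tot <- 0L
    for (i in idx) {
      kmax <- if (include_3mers) 3L else 2L
      if (hc[i] >= 1L && hc[i] <= kmax) {
        tot <- tot + 1L
        rs <- ionflow:::hri_ranges[[as.character(hc[i])]]
        if (in_any(v100[i], rs)) hri <- hri + 1L
      }
    }
    if (tot == 0L || hri / tot <= max_frac) return(k)
  }
}

test_that("HRI range membership is exact on the hundredth grid", {
  o <- tacg_order()
  hri1 <- function(v) ionflow:::is_hri_flow(as.integer(round(v * 100)),
                                            as.integer(floor(v + 0.5 + 1e-6)))
  expect_true(hri1(1.45))    # 1-mer high residual
  expect_true(hri1(0.50))
  expect_true(hri1(0.59))
  expect_false(hri1(0.49))   # negative flow, not HRI
  expect_false(hri1(0.60))
  expect_true(hri1(1.50))    # 2-mer
  expect_true(hri1(2.41))
  expect_false(hri1(2.50))   # 3-mer only with include_3mers
  expect_true(ionflow:::is_hri_flow(250L, 3L, include_3mers = TRUE))
  expect_true(ionflow:::is_hri_flow(340L, 3L, include_3mers = TRUE))
})

test_that("reads with no HRI flows are left unclipped", {
  rd <- fake_sff_read(c(1.0, 2.0, 0.1, 1.0, 3.0, 1.02))
  tr <- hri_trim(rd)
  expect_identical(tr$flows_retained, 6L)
  expect_identical(tr$clip[2], nchar(rd$bases))
  expect_false(tr$discarded)
})

test_that("HRI trimming equals the brute-force suffix scan exactly", {
  set.seed(17)
  for (i in 1:300) {
    nf <- sample(8:48, 1)
    v <- round(stats::runif(nf, 0, 3.6), 2)
    rd <- fake_sff_read(v, samba_order())
    for (incl3 in c(FALSE, TRUE)) {
      tr <- hri_trim(rd, include_3mers = incl3)
      expect_identical(tr$flows_retained, hri_oracle(rd, incl3))
      expect_identical(tr$clip[2],
                       sum(tabulate(rd$flow_of_base + 1L,
                                    nf)[seq_len(tr$flows_retained)]))
    }
  }
})

test_that("reads shorter than 4 bases after clipping are discarded", {
  rd <- fake_sff_read(rep(1.45, 10))   # every flow is an HRI 1-mer
  tr <- hri_trim(rd)
  expect_identical(tr$flows_retained, 0L)
  expect_true(tr$discarded)
})

test_that("effective clips combine SFF fields and the windowed fallback", {
  rd <- fake_sff_read(rep(1.0, 40))          # 40 bases, q30
  expect_identical(effective_clip(rd), c(1L, 40L))
  rd$clip_qual <- c(1L, 25L)
  expect_identical(effective_clip(rd), c(1L, 25L))
  rd$clip_adapter <- c(3L, 30L)
  expect_identical(effective_clip(rd), c(3L, 25L))  # more stringent of both
  rd$clip_qual <- c(1L, 90L)
  rd$clip_adapter <- c(0L, 0L)
  expect_identical(effective_clip(rd)[2], 40L)      # capped at read end
  # fallback: mean quality <= 9 over a 30 bp window clips the tail
  rd2 <- fake_sff_read(rep(1.0, 60),
                       qualities = c(rep(30L, 25), rep(5L, 35)))
  clip <- effective_clip(rd2)
  expect_lt(clip[2], 60L)
})

test_that("empirical quality recovers exact error rates and bounds", {
  sff <- list(reads = list(
    list(name = "r1", qualities = c(rep(20L, 6), rep(30L, 4)))))
  cols <- data.table::data.table(
    kind = c("match", "match", "match", "sub", "ins", "match",
             "match", "match", "match", "match", "del"),
    name = "r1", read_pos = c(1:10, 5L))
  out <- empirical_quality(cols, sff)
  q20 <- out[out$q == 20L]
  expect_identical(q20$n, 6L)
  expect_identical(q20$errors, 2L)
  expect_equal(q20$empirical_q, -10 * log10(2 / 6))
  q30 <- out[out$q == 30L]
  expect_identical(q30$errors, 0L)
  expect_true(q30$is_bound)
  expect_equal(q30$empirical_q, -10 * log10(3 / 4))  # rule of three
  # 1000 bases at q20 with 10 errors give an empirical quality of 20
  sff2 <- list(reads = list(list(name = "r", qualities = rep(20L, 1000))))
  cols2 <- data.table::data.table(
    kind = c(rep("sub", 10), rep("match", 990)),
    name = "r", read_pos = 1:1000)
  expect_equal(empirical_quality(cols2, sff2)$empirical_q, 20)
})

test_that("homopolymer quality profiles follow the relative-change formula", {
  o <- tacg_order()
  rd <- fake_sff_read(c(3.0, 1.0), o, qualities = c(30L, 27L, 24L, 30L))
  sff <- list(reads = list(rd), order = o)
  obs <- data.table::data.table(name = "r1", flow = 0:1,
                                h_true = c(3L, 1L), h_called = c(3L, 1L),
                                sub = FALSE)
  prof <- hp_quality_profile(obs, sff, n_sample = 10L, seed = 1)$profile
  cor <- prof[prof$group == "correct"]
  expect_equal(cor$mean_rel_change, c(0, 0.1, 0.2))
  # over-called flows are reported separately
  obs2 <- data.table::copy(obs)[flow == 0L, h_true := 2L]
  prof2 <- hp_quality_profile(obs2, sff, n_sample = 10L, seed = 1)$profile
  expect_setequal(unique(prof2$group), "over_call")
})

test_that("treatment metrics reconcile and improve with HRI trimming", {
  tr <- tiny_run(n_reads = 250L, sub_rate = 5e-4)
  pr <- profile_run(tr$sim$sff, tr$sim$sam, tr$genome, kit = NULL)
  trims <- trim_reads(tr$sim$sff, "OT100")
  expect_identical(nrow(trims), 250L * 4L)
  expect_true(all(trims$retained >= 0))
  # clip nesting: each added treatment can only shorten the read
  wide <- data.table::dcast(trims, name ~ treatment, value.var = "clip_end")
  expect_true(all(wide$`AT+QT` <= wide$AT))
  expect_true(all(wide$`AT+QT+HRI` <= wide$`AT+QT`))
  met <- kit_metrics(trims, pr$columns)
  expect_identical(nrow(met), 4L)
  at <- met[met$treatment == "AT"]
  hri <- met[met$treatment == "AT+QT+HRI"]
  # noise grows along the read, so HRI trimming cannot hurt
  expect_lte(hri$ins_rate + hri$del_rate, at$ins_rate + at$del_rate)
  expect_gte(hri$pct_error_free, at$pct_error_free)
  expect_lte(met[met$treatment == "AT+QT"]$pct_data_retained, 100)
  # percentile definition agrees with a sort-based oracle
  lens <- trims[trims$treatment == "AT" & !trims$discarded]$retained
  srt <- sort(lens)
  expect_equal(at$len_p50, srt[ceiling(0.5 * length(srt))])
})

test_that("a noiseless run is error-free under every treatment", {
  tr <- tiny_run(n_reads = 50L, sub_rate = 0,
                 mean_params = dglm_params(beta_h = 1),
                 disp_params = dglm_params(intercept = -40),
                 zero_flow = c(mean = 0, sd = 1e-9))
  pr <- profile_run(tr$sim$sff, tr$sim$sam, tr$genome, kit = NULL)
  trims <- trim_reads(tr$sim$sff, "OT100")
  met <- kit_metrics(trims, pr$columns)
  expect_true(all(met$ins_rate == 0))
  expect_true(all(met$del_rate == 0))
  expect_true(all(met$pct_error_free == 100))
})
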