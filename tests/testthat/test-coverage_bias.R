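test_that("run normalisation conserves a unit mean and sqrt transform", {
  rec <- data.table::data.table(
    contig = "c", start = seq(1, 901, 100), gc = runif(10),
    raw_cov = c(rep(10, 9), 40), species = "s")
  out <- normalise_and_transform(rec)
  expect_equal(mean(out$norm_cov), 1, tolerance = 1e-12)
  # constant coverage: y = 1 everywhere
  const <- normalise_and_transform(
    data.table::data.table(contig = "c", start = 1:4, gc = 0.5,
                           raw_cov = 4, species = "s"))
  expect_equal(const$y, rep(1, 4))
  # a window at 4x the run mean transforms to y = 2
  four <- normalise_and_transform(
    data.table::data.table(contig = "c", start = 1:5, gc = 0.5,
                           raw_cov = c(1, 1, 1, 1, 16) * 0.25,
                           species = "s"))
  expect_equal(four$norm_cov[5], 4, tolerance = 1e-12)
  expect_equal(four$y[5], 2, tolerance = 1e-12)
  # doubling raw coverage leaves y unchanged
  out3 <- normalise_and_transform(data.table::copy(rec)[, raw_cov := raw_cov * 2])
  expect_equal(out3$y, out$y)
  expect_error(normalise_and_transform(
    data.table::copy(rec)[, raw_cov := 0]), "zero mean")
})

test_that("window statistics respect masks, ends and uniform depth", {
  g <- simulate_reference(3000, 0.5, seed = 61)
  recs <- data.table::data.table(pos = rep(1L, 5), ref_width = 3000L,
                                 strand = "+")
  ws <- window_stats(recs, g, window = 100L, end_exclusion = 120L)
  expect_true(all(ws$raw_cov == 5))              # uniform depth 5
  expect_true(all(ws$start > 120 & ws$start + 99 <= 3000 - 120))
  gc_direct <- vapply(ws$start, function(s)
    mean(strsplit(substr(g, s, s + 99), "")[[1]] %in% c("G", "C")),
    numeric(1))
  expect_equal(ws$gc, gc_direct)
  m <- mask_set("sim_contig", 500L, 501L)
  ws2 <- window_stats(recs, g, mask = m)
  expect_false(any(ws2$start <= 500 & ws2$start + 99 >= 500))
  expect_identical(nrow(ws) - nrow(ws2), 1L)
})

test_that("the G+C model recovers planted coefficients", {
  # zero noise: exact coefficients
  w0 <- simulate_window_coverage(200, intercept = 0.7, slope = 0.6,
                                 noise_sd = 0, mean_cov = 50, seed = 3)
  # noise-free input gives a perfect lm fit; its summary warning is expected
  f0 <- suppressWarnings(fit_gc_model(normalise_and_transform(w0)))
  # normalisation rescales by sqrt(mean norm cov); undo for comparison
  sc <- sqrt(mean(w0$raw_cov) / 50)
  expect_equal(f0$per_species$slope * sc, 0.6, tolerance = 1e-10)
  expect_equal(f0$per_species$intercept * sc, 0.7, tolerance = 1e-10)
  # two species with opposite slopes keep their signs
  wa <- simulate_window_coverage(300, slope = 0.8, seed = 5,
                                 species = "S.tokodaii")
  wb <- simulate_window_coverage(300, intercept = 1.2, slope = -0.5,
                                 seed = 6, species = "B.amyloliquefaciens")
  wb[, start := start + 1e6]
  both <- rbind(normalise_and_transform(wa), normalise_and_transform(wb))
  fit <- fit_gc_model(both)
  s <- fit$per_species
  expect_gt(s$slope[s$species == "S.tokodaii"], 0)
  expect_lt(s$slope[s$species == "B.amyloliquefaciens"], 0)
  expect_error(fit_gc_model(both[1:10]), "at least 30")
  const <- data.table::copy(both)[, gc := 0.4]
  expect_error(fit_gc_model(const), "unidentifiable")
})

test_that("model fit is invariant to window order", {
  w <- normalise_and_transform(simulate_window_coverage(400, seed = 9))
  f1 <- fit_gc_model(w)
  f2 <- fit_gc_model(w[rev(seq_len(nrow(w)))])
  expect_equal(f1$per_species, f2$per_species)
})

test_that("read-level coverage of uniform starts is flat in expectation", {
  tr <- tiny_run(n_reads = 500L, sub_rate = 0)
  sam <- data.table::as.data.table(tr$sim$sam)
  sam[, ref_width := vapply(cigar_ops(cigar), function(o)
    sum(o$len[o$op %in% c("M", "D")]), integer(1))]
  ws <- window_stats(sam, tr$genome, end_exclusion = 120L)
  nt <- normalise_and_transform(ws)
  # Lander-Waterman: normalised coverage near 1 everywhere
  expect_lt(stats::sd(nt$norm_cov) / mean(nt$norm_cov), 0.5)
  expect_equal(mean(nt$norm_cov), 1, tolerance = 1e-12)
})
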