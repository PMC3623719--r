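# exhaustive oracles, independent of the tested code paths
binom_upper_oracle <- function(x, n, p) sum(stats::dbinom(x:n, n, p))

fisher_two_sided_oracle <- function(x_f, n_f, x_r, n_r) {
  # condition on margins; sum hypergeometric probabilities <= observed
  m <- x_f + x_r
  support <- max(0L, m - n_r):min(m, n_f)
  pr <- stats::dhyper(support, n_f, n_r, m)
  p_obs <- stats::dhyper(x_f, n_f, n_r, m)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

test_that("site binomial p-values equal the exact tail sum", {
  p <- binom_upper_oracle(5, 50, 0.01)
  expect_equal(stats::pbinom(4, 50, 0.01, lower.tail = FALSE), p,
               tolerance = 1e-12)
  pl <- data.table::data.table(
    pos = 1:4, h = c(1L, 1L, 2L, 3L),
    cov_fwd = c(25L, 25L, 25L, 25L), cov_rev = c(25L, 25L, 25L, 25L),
    sub_fwd = c(0L, 3L, 0L, 0L), sub_rev = c(0L, 2L, 0L, 0L),
    ins_fwd = c(5L, 0L, 0L, 0L), ins_rev = c(0L, 0L, 0L, 0L),
    del_fwd = c(0L, 0L, 2L, 0L), del_rev = c(0L, 0L, 2L, 1L))
  nr <- list(sub_rate = 0.01,
             indel_rate = data.table::data.table(h = 1:3, rate = c(0.01, 0.02, 0.03),
                                                 n = 1e4),
             h_cap = 3L)
  tests <- site_binomial_tests(pl, nr)
  for (i in seq_len(nrow(tests))) {
    p0 <- if (tests$type[i] == "sub") 0.01 else
      nr$indel_rate$rate[match(tests$h[i], nr$indel_rate$h)]
    expect_equal(tests$p_raw[i],
                 binom_upper_oracle(tests$x[i], tests$n[i], p0),
                 tolerance = 1e-12)
  }
  expect_true(all(tests$p_holm >= tests$p_raw))
  # x = 0 sites are not reported but would have p = 1
  expect_false(any(tests$x == 0L))
})

test_that("insertion coverage is the maximum of the adjacent bases", {
  pl <- data.table::data.table(
    pos = 1:3, h = 1L, cov_fwd = c(10L, 30L, 20L), cov_rev = 0L,
    sub_fwd = 0L, sub_rev = 0L, ins_fwd = c(4L, 0L, 0L), ins_rev = 0L,
    del_fwd = 0L, del_rev = 0L)
  nr <- list(sub_rate = 0.01,
             indel_rate = data.table::data.table(h = 1L, rate = 0.01, n = 1e4),
             h_cap = 1L)
  tests <- site_binomial_tests(pl, nr)
  ins <- tests[tests$type == "ins"]
  expect_identical(ins$n, 30L)  # max(cov at pos 1, cov at pos 2)
})

test_that("Holm adjustment follows the step-down formula", {
  expect_equal(holm_adjust(c(0.001, 0.01, 0.04)), c(0.003, 0.02, 0.04))
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(rep(0.02, 4)), rep(0.08, 4))
  p <- c(0.2, 1e-5, 0.9, 0.004)
  # hand-rolled step-down: p'(i) = max_{j<=i} min(1, (m-j+1) p_(j))
  o <- order(p); m <- 4
  hand <- cummax(pmin(1, (m - seq_len(m) + 1) * p[o]))[order(o)]
  expect_equal(holm_adjust(p), hand)
})

test_that("Fisher strand tests equal the hypergeometric enumeration", {
  # [[5,0],[0,5]] -> 2 / choose(10,5)
  expect_equal(fisher_two_sided_oracle(5, 5, 0, 5), 2 / choose(10, 5))
  sites <- data.table::data.table(pos = 1:3, h = 2L, type = "del",
                                  x = 5L, n = 10L, p_raw = 1e-9,
                                  p_holm = 1e-8, significant = TRUE)
  pl <- data.table::data.table(
    pos = 1:3, h = 2L, cov_fwd = c(5L, 6L, 8L), cov_rev = c(5L, 6L, 0L),
    sub_fwd = 0L, sub_rev = 0L, ins_fwd = 0L, ins_rev = 0L,
    del_fwd = c(5L, 3L, 4L), del_rev = c(0L, 3L, 0L))
  res <- strand_asymmetry_tests(sites, pl)
  expect_equal(res$asym_p_raw[1], 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$asym_p_raw[2], 1)          # perfectly balanced
  expect_false(res$testable[3])               # single-strand site
  expect_true(is.na(res$asym_p_holm[3]))
  set.seed(8)
  for (i in 1:60) {                           # random tables, n <= 40
    n_f <- sample(1:20, 1); n_r <- sample(1:20, 1)
    x_f <- sample(0:n_f, 1); x_r <- sample(0:n_r, 1)
    ours <- stats::fisher.test(matrix(c(x_f, n_f - x_f, x_r, n_r - x_r),
                                      2, byrow = TRUE))$p.value
    expect_equal(ours, fisher_two_sided_oracle(x_f, n_f, x_r, n_r),
                 tolerance = 1e-12)
  }
})

test_that("null rate estimation recovers generative rates and pools tails", {
  g <- simulate_reference(30000, 0.45, seed = 31)
  pl <- simulate_site_pileups(g, coverage = 100, sub_rate = 3e-4,
                              indel_rate_base = 2e-3, seed = 32)
  nr <- suppressWarnings(estimate_null_rates(pl))
  expect_lt(abs(nr$sub_rate - 3e-4) / 3e-4, 0.3)
  r1 <- nr$indel_rate$rate[nr$indel_rate$h == 1L]
  expect_lt(abs(r1 - 2 * 2e-3) / (2 * 2e-3), 0.15)  # ins + del at h = 1
  expect_error(estimate_null_rates(pl[1:3]), "10\\^4")
})

test_that("planted sites are detected and clean genomes stay clean", {
  g <- simulate_reference(10000, 0.45, seed = 41)
  planted <- plant_hfi_sites(g, 5e-4, penetrance = 0.3, asym_fraction = 0,
                             seed = 42)
  pl <- simulate_site_pileups(g, coverage = 100, planted = planted,
                              seed = 43)
  nr <- suppressWarnings(estimate_null_rates(pl))
  tests <- site_binomial_tests(pl, nr)
  sig <- tests[tests$significant & tests$type %in% c("ins", "del")]
  expect_true(all(planted$pos %in% sig$pos))   # full power at pen 0.3
  fp <- setdiff(sig$pos, planted$pos)
  expect_lte(length(fp), 1L)
})

test_that("strand-restricted planted sites show Fisher asymmetry", {
  g <- simulate_reference(10000, 0.45, seed = 51)
  planted <- plant_hfi_sites(g, 3e-4, penetrance = 0.4, asym_fraction = 1,
                             seed = 52)
  pl <- simulate_site_pileups(g, coverage = 200, planted = planted,
                              seed = 53)
  nr <- suppressWarnings(estimate_null_rates(pl))
  tests <- site_binomial_tests(pl, nr)
  asym <- strand_asymmetry_tests(tests, pl)
  hits <- asym[asym$asym_significant]
  expect_true(all(planted$pos %in% asym$pos))
  expect_gt(mean(planted$pos %in% hits$pos), 0.8)
})

test_that("site-set intersection reports overlaps and unique fractions", {
  a <- data.table::data.table(pos = c(1L, 2L, 3L), type = "del")
  b <- data.table::data.table(pos = c(2L, 3L, 4L), type = "del")
  res <- intersect_sites(list(runA = a, runB = b))
  expect_identical(res$pairwise["runA", "runB"], 2L)
  expect_identical(res$shared_all, 2L)
  expect_equal(unname(res$unique_fraction), c(1 / 3, 1 / 3))
  res2 <- intersect_sites(list(a = a, b = a))
  expect_equal(unname(res2$unique_fraction), c(0, 0))
  expect_error(intersect_sites(list(a)), ">= 2")
})

test_that("HFI masks cover sites and insertion junction flanks", {
  sites <- data.table::data.table(
    pos = c(10L, 20L, 30L), h = 1L, type = c("del", "ins", "sub"),
    x = 5L, n = 50L, p_raw = 1e-9, p_holm = 1e-8,
    significant = c(TRUE, TRUE, FALSE))
  m <- hfi_mask(sites, "c")
  bits <- mask_bits(m, "c", 40L)
  expect_true(bits[10]); expect_false(bits[11])
  expect_true(all(bits[20:21]))   # insertion masks both flanks
  expect_false(bits[30])          # not significant
  expect_identical(nrow(hfi_mask(sites[significant == FALSE])), 0L)
})
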