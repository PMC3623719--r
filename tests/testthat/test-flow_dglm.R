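table3 <- pgm_flow_model()

# look up the generative value behind a fitted coefficient name
eval_coef <- function(params, nm) {
  switch(nm,
         "(Intercept)" = params$intercept,
         h = params$beta_h,
         cycle = params$beta_cycle,
         speciesS.tokodaii = unname(params$species["S.tokodaii"]),
         chip316 = unname(params$chip["316"]),
         kitM200 = unname(params$kit["M200"]),
         kitOT200 = unname(params$kit["OT200"]),
         stop("unexpected coefficient ", nm))
}

test_that("degenerate models reduce to closed forms", {
  set.seed(2)
  n <- 2000
  y <- stats::rnorm(n, 1.5, 0.3)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- ionflow:::fit_dglm_design(X, y, c("(Intercept)" = "(Intercept)"))
  expect_equal(unname(fit$mean), mean(y), tolerance = 1e-10)
  # dispersion intercept is the log of the ML (divide-by-n) variance
  expect_equal(unname(exp(fit$dispersion)), mean((y - mean(y))^2),
               tolerance = 1e-8)
})

test_that("with constant variance the DGLM mean equals OLS", {
  set.seed(3)
  n <- 5000
  dat <- data.table::data.table(
    h = sample(1:5, n, TRUE), cycle = sample(0:9, n, TRUE), pic = 0L,
    species = "B.amyloliquefaciens", chip = "314", kit = "OT100")
  dat[, y := 0.05 + 0.97 * h - 0.001 * cycle + stats::rnorm(n, 0, 0.1)]
  fit <- fit_dglm(dat, disp_columns = "(Intercept)")
  ols <- stats::lm(y ~ h + cycle, data = dat)
  expect_equal(unname(fit$mean[c("(Intercept)", "h", "cycle")]),
               unname(stats::coef(ols)), tolerance = 1e-8)
})

test_that("the fit recovers the published generative coefficients", {
  obs <- simulate_flow_observations(1.5e5, table3$mean, table3$dispersion,
                                    seed = 6)
  fit <- fit_dglm(obs)
  expect_lte(fit$iterations, 50L)
  for (nm in names(fit$mean)) {
    truth <- eval_coef(table3$mean, nm)
    expect_lt(abs(fit$mean[[nm]] - truth), 0.01)
  }
  for (nm in names(fit$dispersion)) {
    truth <- eval_coef(table3$dispersion, nm)
    expect_lt(abs(fit$dispersion[[nm]] - truth), 0.1)
  }
  # order invariance
  fit2 <- fit_dglm(obs[sample.int(nrow(obs))])
  expect_equal(fit$mean, fit2$mean, tolerance = 1e-6)
  expect_true(all(fit$fitted_sigma2 > 0))
})

test_that("assembling observations drops zero flows and subsamples", {
  obs <- data.table::data.table(
    y = stats::runif(1000), h_true = sample(0:3, 1000, TRUE),
    cycle = 0L, pic = 0L, sub = FALSE)
  runs <- list(list(observations = obs, metadata = run_metadata("r1")))
  dt <- assemble_observations(runs, 500, seed = 1)
  expect_identical(nrow(dt), 500L)
  expect_true(all(dt$h >= 1L))
  dt2 <- assemble_observations(runs, 500, seed = 1)
  expect_identical(dt, dt2)                       # seed-reproducible
  obs0 <- data.table::copy(obs)[, h_true := 0L]
  expect_error(assemble_observations(
    list(list(observations = obs0, metadata = run_metadata("r1"))), 500,
    seed = 1), "no usable")
  expect_error(assemble_observations(runs, 5, seed = 1), "10x")
})

test_that("practically unimportant terms are dropped on refit", {
  set.seed(9)
  n <- 20000
  dat <- data.table::data.table(
    h = sample(1:5, n, TRUE), cycle = sample(0:9, n, TRUE), pic = 0L,
    species = sample(c("B.amyloliquefaciens", "S.tokodaii"), n, TRUE),
    chip = "314", kit = "OT100")
  # species effect far below the 0.001 retention threshold in both parts
  dat[, y := 0.05 + 0.97 * h - 0.01 * cycle +
        1e-5 * (species == "S.tokodaii") + stats::rnorm(n, 0, 0.02)]
  fit <- fit_dglm(dat)
  red <- retain_terms(fit)
  expect_true("species" %in% red$dropped)
  expect_false(any(grepl("species", names(red$fit$mean))))
  # with threshold 0 nothing is dropped
  expect_length(retain_terms(fit, threshold = 0)$dropped, 0)
  cmp <- compare_models(fit, red$fit)
  expect_gte(cmp$lr, 0)
  expect_identical(cmp$df, 2L)
  same <- compare_models(fit, fit)
  expect_equal(same$lr, 0)
  expect_equal(same$p_value, 1)
  # dropping a real term is decisively rejected
  Xr <- ionflow:::dglm_model_matrix(dat)[, c("(Intercept)", "cycle")]
  noh <- ionflow:::fit_dglm_design(Xr, dat$y,
                                   c("(Intercept)", "cycle"))
  expect_lt(compare_models(fit, noh)$p_value, 1e-10)
})

test_that("predicted densities are normal curves that integrate to one", {
  obs <- simulate_flow_observations(5e4, table3$mean, table3$dispersion,
                                    seed = 12)
  fit <- fit_dglm(obs)
  dens <- predict_density(fit, h_list = 1:3, grid = seq(-2, 8, by = 0.01))
  for (hh in 1:3) {
    d <- dens[dens$h == hh]
    expect_equal(sum(d$density) * 0.01, 1, tolerance = 1e-3)
  }
  m1 <- dens[dens$h == 1][which.max(density)]$y
  m2 <- dens[dens$h == 2][which.max(density)]$y
  expect_equal(m2 - m1, fit$mean[["h"]], tolerance = 0.02)
  expect_error(predict_density(fit, h_list = 0), "outside the model")
})

test_that("zero-flow over-call rates match the Gaussian tail closed form", {
  zf <- c(mean = 0.3, sd = 0.15)
  tr <- tiny_run(n_reads = 500L, sub_rate = 0, zero_flow = zf)
  led <- tr$sim$ledger
  led[, sub := as.logical(sub)]
  zr <- zero_overcall_rates(led[, .(name, flow, h_true, h_called,
                                    sub, pic = flow %% 32L,
                                    cycle = flow %/% 32L)])
  overall <- sum(zr$n * zr$overcall_rate) / sum(zr$n)
  # truncated-at-zero normal: P(y >= 0.495 | y > 0)
  expected <- stats::pnorm(0.495, 0.3, 0.15, lower.tail = FALSE) /
    stats::pnorm(0, 0.3, 0.15, lower.tail = FALSE)
  expect_gt(sum(zr$n), 10000)
  expect_lt(abs(overall - expected) / expected, 0.15)
  # noiseless zero flows never over-call
  tr0 <- tiny_run(n_reads = 60L, sub_rate = 0,
                  zero_flow = c(mean = 0, sd = 1e-9))
  expect_identical(sum(tr0$sim$ledger[h_true == 0L]$h_called), 0L)
})
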