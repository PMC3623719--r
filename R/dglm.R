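# Double generalised linear model of flow-values: Gaussian mean and
# log-linear dispersion, fitted by the classical alternating scheme
# (weighted least squares for the mean; gamma GLM with log link on the
# squared residuals for the dispersion).

BASELINES <- c(species = "B.amyloliquefaciens", chip = "314", kit = "OT100")

dglm_model_matrix <- function(data, include_pic = NULL) {
  n <- nrow(data)
  cols <- list("(Intercept)" = rep(1, n), h = as.numeric(data$h),
               cycle = as.numeric(data$cycle))
  terms <- c("(Intercept)" = "(Intercept)", h = "h", cycle = "cycle")
  for (f in c("species", "chip", "kit")) {
    lv <- setdiff(sort(unique(as.character(data[[f]]))), BASELINES[[f]])
    for (l in lv) {
      nm <- paste0(f, l)
      cols[[nm]] <- as.numeric(data[[f]] == l)
      terms[nm] <- f
    }
  }
  if (is.null(include_pic)) include_pic <- length(unique(data$pic)) > 1L
  if (include_pic) {
    for (l in setdiff(sort(unique(data$pic)), 0L)) {
      nm <- paste0("pic", l)
      cols[[nm]] <- as.numeric(data$pic == l)
      terms[nm] <- "pic"
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  attr(X, "term_of") <- terms
  X
}

#' Assemble DGLM input observations from profiled runs
#'
#' Pools flow observations across runs, attaches each run's factor levels,
#' drops true-zero homopolymer flows (zero flows are kept out of the
#' Gaussian model) and substitution-overlapping flows, and draws a uniform
#' subsample without replacement.
#'
#' @param runs List of per-run lists, each with `observations` (from
#'   [profile_run()] or a simulator ledger with columns y, h_true, cycle,
#'   pic, sub) and `metadata` (a [run_metadata]).
#' @param n_subsample Target number of observations (clipped to available).
#' @param seed Integer seed for the subsample.
#' @param h_cap Homopolymer lengths above this are dropped (sparse-tail
#'   instability; default 8).
#' @return `data.table` with columns y, h, cycle, pic, species, chip, kit.
#' @export
assemble_observations <- function(runs, n_subsample, seed, h_cap = 8L) {
  pooled <- data.table::rbindlist(lapply(runs, function(r) {
    obs <- data.table::as.data.table(r$observations)
    if ("h_true" %in% names(obs)) data.table::setnames(obs, "h_true", "h")
    if (!"sub" %in% names(obs)) obs[, sub := FALSE]
    obs <- obs[h >= 1L & h <= h_cap & sub == FALSE,
               c("y", "h", "cycle", "pic")]
    obs[, `:=`(species = r$metadata$species_label,
               chip = r$metadata$chip, kit = r$metadata$kit)]
    obs
  }))
  if (!nrow(pooled)) stop("no usable observations (all h = 0?)")
  # parameter count from one row per factor combination (not the full data)
  rep_rows <- pooled[!duplicated(paste(species, chip, kit, pic))]
  n_par <- ncol(dglm_model_matrix(rep_rows))

  if (n_subsample < 10 * n_par)
    stop("n_subsample must be at least 10x the parameter count (",
         10 * n_par, ")")
  set.seed(substream_seed(seed, "subsample"))
  if (n_subsample < nrow(pooled))
    pooled <- pooled[sample.int(nrow(pooled), n_subsample)]
  pooled[]
}

#' Fit the double generalised linear model of flow-values
#'
#' Alternates (i) weighted least squares for the Gaussian mean with weights
#' 1 / fitted variance and (ii) a gamma GLM with log link on the squared
#' mean residuals for the log-variance, until the largest absolute
#' coefficient change falls below `tol`. Both linear predictors share the
#' same structure: homopolymer length and cycle as numeric covariates;
#' species, chip, kit and (when present) position-in-cycle as
#' treatment-coded factors with baselines B. amyloliquefaciens / 314 /
#' OT100 / PIC 0.
#'
#' @param data Observation table from [assemble_observations()] or
#'   [simulate_flow_observations()] (columns y, h, cycle, pic, species,
#'   chip, kit).
#' @param tol Convergence tolerance on the max absolute coefficient change
#'   (default 1e-8).
#' @param max_iter Maximum outer iterations (default 50).
#' @param include_pic Force inclusion/exclusion of PIC factor columns
#'   (default: included when more than one PIC value is present).
#' @param disp_columns Column names of the dispersion design (default: the
#'   full mean design; `"(Intercept)"` alone gives the homoscedastic
#'   model, in which the mean coefficients equal ordinary least squares).
#' @return A `dglm_fit`: list with `mean` and `dispersion` (named
#'   coefficient vectors), `n_obs`, `iterations`, `final_change`,
#'   `log_likelihood`, `fitted_mu`, `fitted_sigma2` and the design matrix
#'   metadata.
#' @export
fit_dglm <- function(data, tol = 1e-8, max_iter = 50L, include_pic = NULL,
                     disp_columns = NULL) {
  stopifnot(all(c("y", "h", "cycle") %in% names(data)))
  if (length(unique(data$h)) < 2L)
    stop("need at least two distinct homopolymer lengths")
  X <- dglm_model_matrix(data, include_pic)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design matrix is rank deficient; aliased columns: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
               collapse = ", "))
  Z <- if (is.null(disp_columns)) X else {
    stopifnot(all(disp_columns %in% colnames(X)))
    X[, disp_columns, drop = FALSE]
  }
  fit <- fit_dglm_design(X, data$y, attr(X, "term_of"), tol = tol,
                         max_iter = max_iter, Z = Z)
  if (fit$final_change > tol)
    stop("DGLM did not converge in ", max_iter,
         " iterations (last change ", signif(fit$final_change, 3), ")")
  fit$data <- data
  fit
}

#' @export
print.dglm_fit <- function(x, ...) {
  cat("<dglm_fit> n =", x$n_obs, "| converged in", x$iterations,
      "iterations | logLik", format(x$log_likelihood, digits = 8), "\n")
  disp <- x$dispersion[names(x$mean)]
  tab <- data.frame(mean = x$mean, dispersion = unname(disp))
  print(signif(tab, 5))
  invisible(x)
}

#' Drop practically unimportant terms and refit
#'
#' A term's effect size is the largest absolute contribution it makes to
#' the modeled flow-value (the mean linear predictor) over the training
#' data: |coefficient| x max |x| for numeric covariates, max |level
#' coefficient| for factors, which are dropped only when every level
#' qualifies. Terms at or below `threshold` are removed from both
#' predictors and the model refitted.
#'
#' @param fit A `dglm_fit`.
#' @param threshold Effect-size threshold (default 0.001).
#' @return List with `fit` (the refitted reduced model, or the original if
#'   nothing was dropped) and `dropped` (character vector of term names).
#' @export
retain_terms <- function(fit, threshold = 0.001) {
  data <- fit$data
  X <- dglm_model_matrix(data, fit$include_pic)
  term_of <- attr(X, "term_of")
  e <- vapply(colnames(X), function(cn)
    max(abs(fit$mean[cn] * X[, cn])), numeric(1))
  keep_col <- e > threshold | term_of == "(Intercept)"
  term_keep <- tapply(keep_col, term_of, any)   # factor kept if any level is
  dropped <- names(term_keep)[!term_keep]
  if (!length(dropped)) return(list(fit = fit, dropped = character(0)))
  keep <- term_of %in% names(term_keep)[term_keep]
  refit <- fit_dglm_design(X[, keep, drop = FALSE], data$y,
                           term_of[keep])
  refit$data <- data
  list(fit = refit, dropped = dropped)
}

# alternating fit on explicit design matrices (mean X, dispersion Z)
fit_dglm_design <- function(X, y, term_of, tol = 1e-8, max_iter = 50L,
                            Z = X) {
  beta <- qr.coef(qr(X), y)
  d <- pmax((y - drop(X %*% beta))^2, 1e-300)
  gamma <- rep(0, ncol(Z))
  it <- 0L; change <- Inf
  while (it < max_iter && change > tol) {
    it <- it + 1L
    old <- c(beta, gamma)
    gamma <- suppressWarnings(stats::glm.fit(
      Z, d, family = stats::Gamma(link = "log"),
      control = list(maxit = 100)))$coefficients
    sigma2 <- pmax(exp(drop(Z %*% gamma)), 1e-300)
    beta <- stats::lm.wfit(X, y, w = 1 / sigma2)$coefficients
    d <- pmax((y - drop(X %*% beta))^2, 1e-300)
    change <- max(abs(c(beta, gamma) - old))
  }
  mu <- drop(X %*% beta)
  sigma2 <- exp(drop(Z %*% gamma))
  structure(list(mean = beta, dispersion = gamma, n_obs = length(y),
                 iterations = it, final_change = change,
                 log_likelihood = sum(stats::dnorm(y, mu, sqrt(sigma2),
                                                   log = TRUE)),
                 term_of = term_of, fitted_mu = mu, fitted_sigma2 = sigma2,
                 include_pic = any(term_of == "pic")),
            class = "dglm_fit")
}

#' Likelihood-ratio comparison of nested DGLM fits
#'
#' Twice the Gaussian log-likelihood difference (using each model's fitted
#' per-observation variances) against a chi-square with the parameter-count
#' difference as degrees of freedom.
#'
#' @param full_fit,reduced_fit `dglm_fit`s on the same observations;
#'   the reduced model's columns must be a subset of the full model's.
#' @return List with `lr`, `df`, `p_value`.
#' @export
compare_models <- function(full_fit, reduced_fit) {
  if (full_fit$n_obs != reduced_fit$n_obs)
    stop("models were fitted to different numbers of observations")
  if (!all(names(reduced_fit$mean) %in% names(full_fit$mean)))
    stop("models are not nested")
  df <- 2L * (length(full_fit$mean) - length(reduced_fit$mean))
  lr <- max(0, 2 * (full_fit$log_likelihood - reduced_fit$log_likelihood))
  p <- if (df == 0L) 1 else stats::pchisq(lr, df, lower.tail = FALSE)
  list(lr = lr, df = df, p_value = p)
}

#' Predicted flow-value densities by homopolymer length
#'
#' Gaussian densities with the fitted mean and variance at the supplied
#' covariates, one curve per homopolymer length (h >= 1; zero flows are
#' outside the model).
#'
#' @param fit A `dglm_fit`.
#' @param h_list Homopolymer lengths to predict for.
#' @param cycle,pic,species,chip,kit Covariate values (scalars).
#' @param grid Numeric grid of flow-values.
#' @return `data.table` with columns h, y, density.
#' @export
predict_density <- function(fit, h_list = 1:5, cycle = 0, pic = 0L,
                            species = BASELINES[["species"]],
                            chip = BASELINES[["chip"]],
                            kit = BASELINES[["kit"]],
                            grid = seq(0, 8, by = 0.01)) {
  if (any(h_list < 1)) stop("h = 0 is outside the model domain")
  out <- lapply(h_list, function(h) {
    nd <- data.table::data.table(y = 0, h = h, cycle = cycle, pic = pic,
                                 species = species, chip = chip, kit = kit)
    Xn <- dglm_model_matrix(nd, fit$include_pic)
    common <- intersect(colnames(Xn), names(fit$mean))
    mu <- sum(Xn[1, common] * fit$mean[common])
    s2 <- exp(sum(Xn[1, common] * fit$dispersion[common]))
    data.table::data.table(h = h, y = grid,
                           density = stats::dnorm(grid, mu, sqrt(s2)))
  })
  data.table::rbindlist(out)
}

#' Zero-length homopolymer over-call rates by position-in-cycle and cycle
#'
#' Zero flows are kept out of the Gaussian DGLM; their over-call rate
#' P(called >= 1 | true h = 0) is summarised empirically per (PIC, cycle)
#' cell with denominators.
#'
#' @param observations Flow-observation table with h_true, h_called, pic,
#'   cycle (substitution-overlapping flows are excluded).
#' @return `data.table`: pic, cycle, n, overcall_rate.
#' @export
zero_overcall_rates <- function(observations) {
  obs <- observations[observations$sub == FALSE & observations$h_true == 0L]
  out <- obs[, .(n = .N, overcall_rate = mean(h_called >= 1L)),
             by = .(pic, cycle)]
  data.table::setorder(out, pic, cycle)
  out[]
}

#' Export a fitted coefficient table
#' @param fit A `dglm_fit`.
#' @return `data.table` with variable, mean_coefficient,
#'   dispersion_coefficient.
#' @export
coef_table <- function(fit) {
  data.table::data.table(variable = names(fit$mean),
                         mean_coefficient = unname(fit$mean),
                         dispersion_coefficient = unname(fit$dispersion))
}
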