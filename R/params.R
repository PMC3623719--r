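#' Coefficients of one linear predictor of the flow-value DGLM
#'
#' The flow-value model has two linear predictors of identical structure:
#' one for the Gaussian mean and one for the log-variance (dispersion).
#' Factors use treatment coding with baselines B. amyloliquefaciens,
#' chip 314, the 100 bp OneTouch kit (OT100) and position-in-cycle 0; the
#' baseline levels carry an implicit coefficient of 0.
#'
#' @param intercept Numeric intercept (value of the predictor at baseline).
#' @param species Named numeric vector of species offsets (non-baseline
#'   levels only, e.g. `c(S.tokodaii = ...)`).
#' @param chip Named numeric vector of chip offsets (e.g. `c("316" = ...)`).
#' @param kit Named numeric vector of kit offsets (levels `M200`, `OT200`).
#' @param beta_h Multiplier of the (numeric) homopolymer length.
#' @param beta_cycle Multiplier of the (numeric, 0-based) flow cycle.
#' @param pic_effects Numeric vector of position-in-cycle offsets, one per
#'   flow position in the order's period; element 1 (PIC 0) must be 0.
#' @return A `dglm_params` list.
#' @export
dglm_params <- function(intercept = 0, species = numeric(0),
                        chip = numeric(0), kit = numeric(0),
                        beta_h = 0, beta_cycle = 0,
                        pic_effects = numeric(0)) {
  if (length(pic_effects) && pic_effects[1] != 0)
    stop("pic_effects are baseline-coded: element 1 (PIC 0) must be 0")
  structure(list(intercept = intercept, species = species, chip = chip,
                 kit = kit, beta_h = beta_h, beta_cycle = beta_cycle,
                 pic_effects = pic_effects),
            class = "dglm_params")
}

lookup0 <- function(coefs, levels) {
  out <- numeric(length(levels))
  hit <- levels %in% names(coefs)
  out[hit] <- coefs[levels[hit]]
  out
}

#' Evaluate a DGLM linear predictor
#' @param params A [dglm_params].
#' @param h,cycle,pic Numeric/integer covariates (PIC 0-based).
#' @param species,chip,kit Factor levels as character vectors (baseline
#'   levels contribute 0).
#' @return Numeric vector of linear-predictor values.
#' @export
eval_predictor <- function(params, h, cycle, pic = 0L,
                           species = "B.amyloliquefaciens",
                           chip = "314", kit = "OT100") {
  lp <- params$intercept + params$beta_h * h + params$beta_cycle * cycle +
    lookup0(params$species, species) + lookup0(params$chip, chip) +
    lookup0(params$kit, kit)
  if (length(params$pic_effects))
    lp <- lp + params$pic_effects[pic + 1L]
  lp
}

#' Published flow-value model coefficients
#'
#' The fitted mean and dispersion coefficients of the double generalised
#' linear model of PGM flow-values: the mean is linear in homopolymer
#' length (coefficient 0.9754, so each extra base shifts the mean down by
#' about 0.025 relative to the ideal integer), cycle number and the run
#' factors; the log-variance grows with homopolymer length (0.486) and
#' cycle (0.147), with large chip and kit offsets. PIC effects default to
#' zero here (they are configurable per order period).
#'
#' @return List with elements `mean` and `dispersion`, each a
#'   [dglm_params].
#' @export
pgm_flow_model <- function() {
  list(
    mean = dglm_params(
      intercept = 4.405e-02,
      species = c(S.tokodaii = -2.606e-03),
      chip = c("316" = -2.527e-03),
      kit = c(M200 = -3.864e-03, OT200 = 6.304e-03),
      beta_h = 9.754e-01,
      beta_cycle = -7.071e-04),
    dispersion = dglm_params(
      intercept = -4.7120481,
      species = c(S.tokodaii = 0.0309340),
      chip = c("316" = 0.2013263),
      kit = c(M200 = 0.0815632, OT200 = -0.2425064),
      beta_h = 0.4862209,
      beta_cycle = 0.1471443))
}
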