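# Weighted linear calibration, back-calculation, and sensitivity metrics.

weight_vector <- function(x, weighting) {
  switch(weighting,
    "none" = rep(1, length(x)),
    "1/x" = 1 / x,
    "1/x2" = ,
    "1/x^2" = 1 / x^2,
    validation_error(sprintf("unknown weighting '%s'", weighting))
  )
}

#' Fit a weighted calibration line
#'
#' Weighted least squares of the analyte/IS response ratio on nominal
#' concentration, with weights 1, 1/x, or 1/x^2. 1/x weighting is the usual
#' choice for LC-MS/MS peak-area data, whose noise grows with concentration.
#' The coefficient of determination is computed on the weighted residuals
#' (`1 - SSE_w/SST_w` about the weighted mean) and the intercept SD is the
#' standard error from the weighted-regression covariance — the quantity the
#' LOD/LOQ formulas consume.
#'
#' @param standards A [calibration_set()] with at least two distinct
#'   nominal concentrations.
#' @param weighting `"1/x"` (default), `"none"`, or `"1/x2"`.
#' @return A list of class `"calibration_model"` with `slope`, `intercept`,
#'   `weighting`, `r_squared`, `intercept_sd`, `n_points`, and the `lm` fit.
#' @export
fit_calibration <- function(standards, weighting = c("1/x", "none", "1/x2")) {
  weighting <- match.arg(weighting)
  x <- standards$nominal_conc
  y <- standards$response_ratio
  if (length(x) < 2) validation_error("at least 2 calibration points required")
  if (length(unique(x)) < 2) {
    validation_error("singular design: all nominal concentrations identical")
  }
  w <- weight_vector(x, weighting)
  fit <- stats::lm(y ~ x, weights = w)
  # summary.lm warns on numerically perfect fits; those are legitimate inputs
  # here (zero-noise simulations, exact lines)
  smry <- suppressWarnings(summary(fit))
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      weighting = weighting,
      r_squared = smry$r.squared,
      intercept_sd = unname(smry$coefficients[1, "Std. Error"]),
      n_points = length(x),
      fit = fit
    ),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Calibration model: y = %.6gx %s %.6g  (weighting %s, n = %d)\n",
              x$slope, ifelse(x$intercept < 0, "-", "+"), abs(x$intercept),
              x$weighting, x$n_points))
  cat(sprintf("  r^2 = %.4f, SD(intercept) = %.6g\n", x$r_squared, x$intercept_sd))
  invisible(x)
}

#' Back-calculate concentrations from response ratios
#'
#' Inverts the calibration line, `x = (y - b) / a`, to convert response
#' ratios into concentrations. Negative back-calculated values (ratios below
#' the intercept) are returned as-is with a flag, never clipped or dropped.
#'
#' @param model A `"calibration_model"`.
#' @param ratios Numeric response ratios.
#' @return A data frame with `response_ratio`, `conc_ng_ml`, and a logical
#'   `flagged_negative` column.
#' @export
back_calculate <- function(model, ratios) {
  if (!is.finite(model$slope) || model$slope == 0) {
    validation_error("calibration slope must be non-zero for back-calculation")
  }
  conc <- (ratios - model$intercept) / model$slope
  data.frame(response_ratio = ratios, conc_ng_ml = conc,
             flagged_negative = conc < 0)
}

#' Limit of detection and quantification
#'
#' Pharmacopeia-style sensitivity limits from the calibration line:
#' `LOD = 3.3 * SD(intercept) / slope` and `LOQ = 10 * SD(intercept) / slope`,
#' so LOQ/LOD is always 10/3.3.
#'
#' @param model A `"calibration_model"` with a positive slope and an
#'   intercept SD.
#' @return Named numeric vector `c(lod = ..., loq = ...)` in ng/mL.
#' @export
lod_loq <- function(model) {
  if (is.null(model$intercept_sd) || !is.finite(model$intercept_sd)) {
    validation_error("intercept SD unavailable; cannot compute LOD/LOQ")
  }
  if (model$slope <= 0) validation_error("LOD/LOQ require a positive slope")
  c(lod = 3.3 * model$intercept_sd / model$slope,
    loq = 10 * model$intercept_sd / model$slope)
}

#' Calibration acceptance per level
#'
#' Back-calculates every standard as an unknown and checks each level's mean
#' accuracy against the bioanalytical acceptance windows (±15% generally,
#' ±20% at the lowest level). The overall curve passes when at least
#' `min_fraction_pass` of the levels pass, the usual guideline convention.
#'
#' @param standards A [calibration_set()].
#' @param model The fitted `"calibration_model"`.
#' @param tolerance_pct Accuracy window in percent for ordinary levels.
#' @param lloq_tolerance_pct Window at the lowest level.
#' @param min_fraction_pass Fraction of levels that must pass overall.
#' @return A list with a per-level data frame (`level`, `mean_conc`,
#'   `re_pct`, `tolerance_pct`, `pass`) and `overall_pass`.
#' @export
calibration_acceptance <- function(standards, model, tolerance_pct = 15,
                                   lloq_tolerance_pct = 20,
                                   min_fraction_pass = 0.75) {
  bc <- back_calculate(model, standards$response_ratio)
  lev <- sort(unique(standards$nominal_conc))
  rows <- lapply(lev, function(nom) {
    m <- mean(bc$conc_ng_ml[standards$nominal_conc == nom])
    tol <- if (nom == min(lev)) lloq_tolerance_pct else tolerance_pct
    re <- 100 * (m - nom) / nom
    data.frame(nominal_conc = nom, mean_conc = m, re_pct = re,
               tolerance_pct = tol, pass = abs(re) <= tol)
  })
  tab <- do.call(rbind, rows)
  list(levels = tab, overall_pass = mean(tab$pass) >= min_fraction_pass)
}
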