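# Substrate-depletion analysis: percent remaining, linear-range selection,
# ln-linear decay fit, in vitro half-life, intrinsic clearance, clearance
# class. The in vitro t1/2 approach assumes first-order parent loss at a
# substrate concentration well below Km.

#' Percent of drug remaining over incubation time
#'
#' Collapses replicates to a per-time mean concentration and expresses each
#' time point as a percentage of the time-0 mean, so X(0) = 100 exactly.
#'
#' @param tc A [time_course()] containing time 0.
#' @return A data frame with `time`, `mean_conc`, and `pct_remaining`.
#' @export
percent_remaining <- function(tc) {
  times <- sort(unique(tc$time))
  if (!0 %in% times) validation_error("time course must contain time 0")
  means <- vapply(times, function(t) mean(tc$measured_conc[tc$time == t]), 0)
  c0 <- means[times == 0]
  if (c0 <= 0) validation_error("zero-time mean concentration must be > 0")
  data.frame(time = times, mean_conc = means, pct_remaining = 100 * means / c0)
}

# r2 computed from residuals directly; summary.lm warns on perfect fits,
# which are routine here (zero-noise simulations, exact exponentials).
ols_r2 <- function(fit, y) {
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) 0 else 1 - sse / sst
}

prefix_r2 <- function(times, lnx, n) {
  fit <- stats::lm(lnx[1:n] ~ times[1:n])
  ols_r2(fit, lnx[1:n])
}

#' Select the ln-linear range of a depletion curve
#'
#' Finds the portion of the curve over which parent loss is still first
#' order. Among contiguous prefixes anchored at t = 0 with at least
#' `min_points` points, returns the longest whose ln-linear fit reaches
#' `r2_min`; if none qualifies, falls back to the best-r-squared prefix with
#' a warning. A manual `range_override = c(t_start, t_end)` is honored
#' verbatim.
#'
#' @param times Time points in minutes (including 0, increasing).
#' @param X Percent remaining at each time (> 0 within the fitted range).
#' @param min_points Minimum points in a candidate prefix (default 4).
#' @param r2_min r-squared threshold for a prefix to qualify (default 0.99).
#' @param range_override Optional `c(t_start, t_end)` to pin the range.
#' @return A list with `t_start`, `t_end`, `n_points`, `r_squared`, and
#'   `qualified` (FALSE when the fallback was used).
#' @export
select_linear_range <- function(times, X, min_points = 4, r2_min = 0.99,
                                range_override = NULL) {
  if (!is.null(range_override)) {
    keep <- times >= range_override[1] & times <= range_override[2]
    r2 <- prefix_r2(times[keep], log(X[keep]), sum(keep))
    return(list(t_start = range_override[1], t_end = range_override[2],
                n_points = sum(keep), r_squared = r2, qualified = TRUE))
  }
  if (length(times) < min_points) {
    validation_error(sprintf("need at least %d time points", min_points))
  }
  if (any(X <= 0)) {
    validation_error(sprintf("non-positive percent remaining at t = %s",
                             times[which(X <= 0)[1]]))
  }
  lnx <- log(X)
  ns <- min_points:length(times)
  r2s <- vapply(ns, function(n) prefix_r2(times, lnx, n), 0)
  ok <- which(r2s >= r2_min)
  if (length(ok) > 0) {
    pick <- max(ok)
    qualified <- TRUE
  } else {
    pick <- which.max(r2s)
    qualified <- FALSE
    warning(sprintf(
      "no prefix reaches r^2 >= %g; falling back to best prefix (0-%g min, r^2 = %.4f)",
      r2_min, times[ns[pick]], r2s[pick]))
  }
  n <- ns[pick]
  list(t_start = times[1], t_end = times[n], n_points = n,
       r_squared = r2s[pick], qualified = qualified)
}

#' Fit the first-order decay rate over a time range
#'
#' Ordinary least squares of `ln(X)` on time within `range`; the decay rate
#' constant is the negated slope.
#'
#' @param times Time points in minutes.
#' @param X Percent remaining (> 0 within the range).
#' @param range `c(t_start, t_end)` in minutes (default: all points).
#' @return A list with `k` (1/min), `ln_intercept`, `r_squared`, and
#'   `n_points`.
#' @export
fit_decay <- function(times, X, range = c(min(times), max(times))) {
  keep <- times >= range[1] & times <= range[2]
  t_fit <- times[keep]
  x_fit <- X[keep]
  if (length(t_fit) < 2) validation_error("decay fit requires at least 2 points")
  if (any(x_fit <= 0)) {
    validation_error(sprintf("ln undefined: percent remaining <= 0 at t = %s",
                             t_fit[which(x_fit <= 0)[1]]))
  }
  fit <- stats::lm(log(x_fit) ~ t_fit)
  list(
    k = -unname(stats::coef(fit)[2]),
    ln_intercept = unname(stats::coef(fit)[1]),
    r_squared = ols_r2(fit, log(x_fit)),
    n_points = length(t_fit)
  )
}

#' In vitro half-life from a first-order rate constant
#'
#' `t1/2 = ln(2) / k` minutes.
#'
#' @param k First-order depletion rate constant in 1/min (> 0).
#' @return Half-life in minutes.
#' @export
half_life <- function(k) {
  # rates at numerical-noise scale mean a flat curve, not slow decay
  if (!is.finite(k) || k < 1e-12) {
    validation_error("no measurable decay: rate constant must be > 0")
  }
  log(2) / k
}

#' Intrinsic clearance from the in vitro half-life
#'
#' Scales the in vitro elimination rate to intrinsic clearance in both unit
#' systems:
#' `CL_int (mL/min/kg) = (0.693 / t1/2) * (mL/mg) * (mg protein/g liver) * (g liver/kg bw)`
#' and `CL_int (uL/min/mg) = (0.693 / t1/2) * (mL/mg) * 1000`. The
#' conventional constant 0.693 is the default numerator; set
#' `decay_constant = log(2)` for the exact value.
#'
#' @param t_half In vitro half-life in minutes (> 0).
#' @param sf [scaling_factors()].
#' @param decay_constant Numerator constant (default 0.693).
#' @return Named numeric vector `c(clint_per_mg = ..., clint_per_kg = ...)`
#'   in uL/min/mg and mL/min/kg.
#' @export
intrinsic_clearance <- function(t_half, sf = scaling_factors(),
                                decay_constant = 0.693) {
  if (!is.finite(t_half) || t_half <= 0) {
    validation_error("half-life must be > 0")
  }
  rate_ml_per_min_mg <- decay_constant / t_half * sf$ml_per_mg
  c(clint_per_mg = rate_ml_per_min_mg * 1000,
    clint_per_kg = rate_ml_per_min_mg * sf$mg_per_g_liver * sf$g_liver_per_kg)
}

#' Classify intrinsic clearance
#'
#' Bands a compound as low / intermediate / high clearance from its
#' intrinsic clearance per mg microsomal protein. Boundary values fall in
#' the intermediate class.
#'
#' @param clint_per_mg Intrinsic clearance in uL/min/mg (>= 0).
#' @param bands [clearance_bands()].
#' @return `"low"`, `"intermediate"`, or `"high"`.
#' @export
classify_clearance <- function(clint_per_mg, bands = clearance_bands()) {
  if (!is.finite(clint_per_mg) || clint_per_mg < 0) {
    validation_error("intrinsic clearance must be >= 0")
  }
  if (clint_per_mg < bands$low_max) "low"
  else if (clint_per_mg > bands$high_min) "high"
  else "intermediate"
}

#' Run the full metabolic-stability analysis
#'
#' Composes the depletion workflow on an incubation time course: percent
#' remaining, linear-range selection, ln-linear decay fit, half-life,
#' intrinsic clearance scaling, and clearance classification. Every
#' intermediate is carried in the result.
#'
#' @param tc A [time_course()].
#' @param sf [scaling_factors()].
#' @param bands [clearance_bands()].
#' @param range_override Optional `c(t_start, t_end)` pinning the linear
#'   range (e.g. `c(0, 30)`).
#' @param min_points,r2_min Passed to [select_linear_range()].
#' @param decay_constant Passed to [intrinsic_clearance()].
#' @return A list of class `"metstab_result"` with the percent-remaining
#'   table, the selected `linear_range`, `k`, `ln_intercept`, `r_squared`,
#'   `t_half`, `clint_per_mg`, `clint_per_kg`, `clearance_class`, and the
#'   scaling factors and bands used.
#' @export
run_metstab <- function(tc, sf = scaling_factors(), bands = clearance_bands(),
                        range_override = NULL, min_points = 4, r2_min = 0.99,
                        decay_constant = 0.693) {
  pr <- percent_remaining(tc)
  rng <- select_linear_range(pr$time, pr$pct_remaining, min_points = min_points,
                             r2_min = r2_min, range_override = range_override)
  dec <- fit_decay(pr$time, pr$pct_remaining, c(rng$t_start, rng$t_end))
  t_half <- half_life(dec$k)
  cl <- intrinsic_clearance(t_half, sf, decay_constant = decay_constant)
  structure(
    list(
      percent_remaining = pr,
      linear_range = c(t_start = rng$t_start, t_end = rng$t_end),
      range_qualified = rng$qualified,
      k = dec$k,
      ln_intercept = dec$ln_intercept,
      r_squared = dec$r_squared,
      t_half = t_half,
      clint_per_mg = unname(cl["clint_per_mg"]),
      clint_per_kg = unname(cl["clint_per_kg"]),
      clearance_class = classify_clearance(unname(cl["clint_per_mg"]), bands),
      scaling_factors = sf,
      clearance_bands = bands
    ),
    class = "metstab_result"
  )
}

#' @export
print.metstab_result <- function(x, ...) {
  cat("In vitro metabolic stability (substrate depletion)\n")
  cat(sprintf("  linear range : %g-%g min (r^2 = %.3f)\n",
              x$linear_range["t_start"], x$linear_range["t_end"], x$r_squared))
  cat(sprintf("  k            : %.4f 1/min\n", x$k))
  cat(sprintf("  t1/2         : %.2f min\n", x$t_half))
  cat(sprintf("  CL_int       : %.2f uL/min/mg  |  %.2f mL/min/kg\n",
              x$clint_per_mg, x$clint_per_kg))
  cat(sprintf("  class        : %s\n", x$clearance_class))
  invisible(x)
}
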