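# Simulators for every input the pipeline consumes, with known ground truth.
# Noise is multiplicative log-normal parameterized by CV (mean exactly 1),
# matching the positive, heteroscedastic character of peak-area data that
# motivates 1/x calibration weighting.

#' Simulation configuration
#'
#' One master configuration for the synthetic-data generators. A fixed seed
#' yields byte-identical outputs; the master seed fans out to independent
#' substreams per table kind so regenerating one table never perturbs
#' another.
#'
#' Defaults emulate the validated assay design: an 8-level calibration from
#' 1 to 3000 ng/mL with a 1/x-weighted linear response, 3% response CV,
#' a depletion time course starting at 584 ng/mL with an operational
#' 0-30 min decay slope of 0.0329 1/min flattening toward a 26% plateau,
#' and unit recovery/matrix-effect ground truths.
#'
#' @param seed Master integer seed.
#' @param cal_levels Calibration levels in ng/mL.
#' @param true_slope,true_intercept Response-line parameters
#'   (ratio per ng/mL, ratio).
#' @param noise_cv Relative SD of multiplicative response noise (>= 0).
#' @param k_true Target 0-30 min ln-linear depletion slope, 1/min.
#' @param plateau_pct Percent-remaining floor (0 <= value < 100).
#' @param c0 Time-0 concentration in ng/mL.
#' @param recovery_true True extraction recovery as a fraction.
#' @param me_true True matrix effect as a fraction.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       cal_levels = c(1, 15, 50, 150, 300, 500, 1500, 3000),
                       true_slope = 1.7298, true_intercept = 3.62941,
                       noise_cv = 0.03, k_true = 0.0329, plateau_pct = 26,
                       c0 = 584, recovery_true = 1, me_true = 1) {
  stopifnot(noise_cv >= 0, plateau_pct >= 0, plateau_pct < 100,
            all(cal_levels > 0), c0 > 0, k_true >= 0)
  structure(
    list(seed = as.integer(seed), cal_levels = cal_levels,
         true_slope = true_slope, true_intercept = true_intercept,
         noise_cv = noise_cv, k_true = k_true, plateau_pct = plateau_pct,
         c0 = c0, recovery_true = recovery_true, me_true = me_true),
    class = "sim_config"
  )
}

# Substream seed: master seed plus a per-table offset, kept inside the
# 32-bit integer range.
sub_seed <- function(seed, stream) {
  offsets <- c(calibration = 1L, timecourse = 2L, qc = 3L,
               matrix_effect = 4L, chromatogram = 5L)
  (abs(seed) %% 1000003L) * 2017L + offsets[[stream]]
}

with_stream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sub_seed(seed, stream))
  force(code)
}

# Multiplicative log-normal noise factors with E[factor] = 1 and the given CV.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Simulate a calibration standard set
#'
#' Generates response ratios on the line
#' `ratio = true_slope * conc + true_intercept`, perturbed multiplicatively
#' with CV `noise_cv`, plus consistent raw peak areas (a log-normal IS area
#' around `is_area_mean` and the analyte area that reproduces the ratio).
#'
#' @param config A [sim_config()].
#' @param replicates Standards per level (default 1).
#' @param is_area_mean Mean IS peak area (arbitrary counts).
#' @return A list with `standards` (a [calibration_set()]) and `truth`
#'   (`slope`, `intercept`, `noise_cv`).
#' @export
simulate_calibration <- function(config, replicates = 1, is_area_mean = 1e5) {
  stopifnot(inherits(config, "sim_config"))
  conc <- rep(config$cal_levels, each = replicates)
  with_stream(config$seed, "calibration", {
    ratio <- (config$true_slope * conc + config$true_intercept) *
      lognormal_noise(length(conc), config$noise_cv)
    is_area <- is_area_mean * lognormal_noise(length(conc), config$noise_cv)
    list(
      standards = calibration_set(conc, analyte_area = ratio * is_area,
                                  is_area = is_area),
      truth = list(slope = config$true_slope, intercept = config$true_intercept,
                   noise_cv = config$noise_cv)
    )
  })
}

# Mechanistic rate r such that the OLS slope of ln(plateau + (100-plateau)
# exp(-r t)) over the window time points equals -k_true. With no plateau the
# operational and mechanistic rates coincide. The operational slope is not
# monotone in r (it peaks and then decays as the curve saturates to the
# plateau inside the window), so the bracket is found by scanning upward and
# the first crossing — the smaller, physically relevant rate — is taken.
solve_mechanistic_rate <- function(k_true, plateau_pct, window_times) {
  if (k_true == 0 || plateau_pct == 0) return(k_true)
  op_slope <- function(r) {
    x <- plateau_pct + (100 - plateau_pct) * exp(-r * window_times)
    -unname(stats::coef(stats::lm(log(x) ~ window_times))[2])
  }
  lower <- k_true
  upper <- k_true
  repeat {
    upper <- upper * 1.25
    if (op_slope(upper) >= k_true) break
    lower <- upper
    if (upper > 1e4 * k_true) {
      validation_error(sprintf(
        "plateau %.3g%% is too high: no mechanistic rate gives an operational slope of %.4g over the linear window",
        plateau_pct, k_true))
    }
  }
  stats::uniroot(function(r) op_slope(r) - k_true, lower = lower, upper = upper,
                 tol = 1e-13)$root
}

#' Simulate a substrate-depletion time course
#'
#' Percent remaining follows
#' `X(t) = plateau_pct + (100 - plateau_pct) * exp(-r t)` with the
#' mechanistic rate `r` solved so that the noiseless ln-linear fit over
#' `linear_window` has slope exactly `-k_true` — the ground truth is thus the
#' operational rate constant the depletion fit is defined to recover.
#' Concentrations are `c0 * X(t) / 100` under multiplicative noise.
#'
#' @param config A [sim_config()].
#' @param times Sampling times in minutes, including 0.
#' @param replicates Replicates per time point (default 3).
#' @param noise_cv Concentration CV (default `config$noise_cv`).
#' @param linear_window `c(t_start, t_end)` defining the operational fit
#'   window (default 0-30 min).
#' @return A list with `tc` (a [time_course()]) and `truth` (`k_eff`,
#'   `t_half_eff`, `rate_mechanistic`, `plateau_pct`, `c0`,
#'   `pct_remaining_true`).
#' @export
simulate_timecourse <- function(config,
                                times = c(0, 2.5, 7.5, 15, 20, 30, 40, 50, 60, 70),
                                replicates = 3, noise_cv = config$noise_cv,
                                linear_window = c(0, 30)) {
  stopifnot(inherits(config, "sim_config"))
  if (any(times < 0)) validation_error("negative incubation time")
  if (!0 %in% times) validation_error("times must include 0")
  window_times <- times[times >= linear_window[1] & times <= linear_window[2]]
  r <- solve_mechanistic_rate(config$k_true, config$plateau_pct, window_times)
  x_true <- config$plateau_pct + (100 - config$plateau_pct) * exp(-r * times)
  conc_true <- config$c0 * x_true / 100
  with_stream(config$seed, "timecourse", {
    grid <- expand.grid(replicate = seq_len(replicates), time = times)
    grid <- grid[order(grid$replicate, grid$time), ]
    conc <- conc_true[match(grid$time, times)] *
      lognormal_noise(nrow(grid), noise_cv)
    list(
      tc = time_course(grid$time, conc, grid$replicate),
      truth = list(k_eff = config$k_true,
                   t_half_eff = if (config$k_true > 0) log(2) / config$k_true else Inf,
                   rate_mechanistic = r, plateau_pct = config$plateau_pct,
                   c0 = config$c0,
                   pct_remaining_true = stats::setNames(x_true, times))
    )
  })
}

#' Simulate a QC replicate table
#'
#' Measured concentrations are `nominal * (1 + bias)` under multiplicative
#' noise, with an optional per-day multiplicative shift to create interday
#' variance.
#'
#' @param config A [sim_config()].
#' @param levels Named vector of nominal concentrations (names are level
#'   labels; default the LLQC/LQC/MQC/HQC design at 1/3/900/2400 ng/mL).
#' @param days Number of days (default 3).
#' @param reps Replicates per level per day (default 6, >= 2).
#' @param bias Fractional accuracy bias (default 0).
#' @param day_shift_cv CV of the per-day multiplicative shift (default 0).
#' @return A list with `qc` (a [qc_table()]) and `truth`.
#' @export
simulate_qc <- function(config,
                        levels = c(LLQC = 1, LQC = 3, MQC = 900, HQC = 2400),
                        days = 3, reps = 6, bias = 0, day_shift_cv = 0) {
  stopifnot(inherits(config, "sim_config"), reps >= 2)
  with_stream(config$seed, "qc", {
    day_shift <- lognormal_noise(days, day_shift_cv)
    grid <- expand.grid(replicate = seq_len(reps), day = seq_len(days),
                        level = names(levels), stringsAsFactors = FALSE)
    nominal <- levels[grid$level]
    measured <- nominal * (1 + bias) * day_shift[grid$day] *
      lognormal_noise(nrow(grid), config$noise_cv)
    list(
      qc = qc_table(grid$level, nominal, grid$day, grid$replicate, measured),
      truth = list(bias = bias, noise_cv = config$noise_cv,
                   day_shift_cv = day_shift_cv, levels = levels)
    )
  })
}

#' Simulate matched matrix / neat sample sets
#'
#' Set 2 (neat solvent) responses scatter around `base_response`; set 1
#' (matrix) responses are the same base response scaled by the true matrix
#' effect, each with independent multiplicative noise. With zero noise the
#' measured matrix effect is exactly `100 * me_true`.
#'
#' @param config A [sim_config()].
#' @param n Samples per set (default 6).
#' @param base_response Mean neat response (arbitrary units).
#' @param analyte_label Label carried on the returned set.
#' @return A list with `me_set` (a [matrix_effect_set()]) and `truth`.
#' @export
simulate_matrix_effect_sets <- function(config, n = 6, base_response = 1e5,
                                        analyte_label = "analyte") {
  stopifnot(inherits(config, "sim_config"), n >= 1)
  with_stream(config$seed, "matrix_effect", {
    set2 <- base_response * lognormal_noise(n, config$noise_cv)
    set1 <- base_response * config$me_true * lognormal_noise(n, config$noise_cv)
    list(
      me_set = matrix_effect_set(set1, set2, analyte_label),
      truth = list(me_true = config$me_true, noise_cv = config$noise_cv)
    )
  })
}

#' Simulate an MRM chromatogram
#'
#' A single-channel trace on a uniform time grid: a sum of Gaussian peaks
#' plus a constant baseline and Gaussian noise, floored at zero counts.
#'
#' @param peaks Data frame with columns `rt` (seconds), `height` (counts),
#'   `width` (Gaussian sigma in seconds, > 0); may have zero rows.
#' @param baseline Constant baseline level in counts.
#' @param noise_sd SD of additive Gaussian noise in counts.
#' @param grid Uniform time grid in seconds.
#' @param seed Seed for the noise draw.
#' @param channel Channel label.
#' @return A list of class `"chromatogram"` with `times`, `intensities`,
#'   and `channel`.
#' @export
simulate_chromatogram <- function(peaks = data.frame(rt = numeric(),
                                                     height = numeric(),
                                                     width = numeric()),
                                  baseline = 0, noise_sd = 0,
                                  grid = seq(0, 180, by = 0.1), seed = 1L,
                                  channel = "MRM") {
  steps <- diff(grid)
  if (length(steps) > 0 && any(abs(steps - steps[1]) > 1e-9 * steps[1])) {
    validation_error("chromatogram grid must be uniform")
  }
  if (nrow(peaks) > 0 && any(peaks$width <= 0)) {
    validation_error("peak widths must be > 0")
  }
  signal <- rep(baseline, length(grid))
  for (i in seq_len(nrow(peaks))) {
    signal <- signal +
      peaks$height[i] * exp(-(grid - peaks$rt[i])^2 / (2 * peaks$width[i]^2))
  }
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    signal <- signal + stats::rnorm(length(grid), sd = noise_sd)
  }
  structure(list(times = grid, intensities = pmax(signal, 0), channel = channel),
            class = "chromatogram")
}

#' Integrate a chromatographic peak
#'
#' Trapezoidal integral of the intensity above a local linear baseline
#' interpolated between the window endpoints, floored at zero. This is the
#' peak-area primitive the simulated MRM responses are built from.
#'
#' @param chrom A `"chromatogram"`.
#' @param window `c(t0, t1)` in seconds, inside the grid.
#' @return Peak area in counts*seconds.
#' @export
integrate_peak <- function(chrom, window) {
  keep <- chrom$times >= window[1] & chrom$times <= window[2]
  t <- chrom$times[keep]
  y <- chrom$intensities[keep]
  if (length(t) < 2) validation_error("empty or degenerate integration window")
  base <- y[1] + (y[length(y)] - y[1]) * (t - t[1]) / (t[length(t)] - t[1])
  h <- y - base
  max(sum((h[-1] + h[-length(h)]) / 2 * diff(t)), 0)
}
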