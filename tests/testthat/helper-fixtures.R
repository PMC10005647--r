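# Shared fixtures and independent oracles.

# Published microsomal depletion time course: per-time mean concentrations
# (ng/mL) at 0..70 min, three replicates already averaged.
depletion_times <- c(0, 2.5, 7.5, 15, 20, 30, 40, 50, 60, 70)
depletion_means <- c(584, 534, 457, 367, 308, 214, 187, 165, 158, 154)

depletion_tc <- function() time_course(depletion_times, depletion_means)

# Published per-level calibration recoveries (%), eleven standards/QCs.
published_recoveries <- c(105.96, 103.59, 102.45, 100.81, 101.38, 98.34,
                          100.57, 99.41, 101.40, 99.75, 100.92)

# Published interday/intraday QC summary cells (mean, SD) at each level.
published_qc_cells <- list(
  intraday = data.frame(
    level = c("LLQC", "LQC", "MQC", "HQC"),
    nominal = c(1, 3, 900, 2400),
    mean = c(1.06, 3.11, 894.72, 2394.09),
    sd = c(0.02, 0.12, 2.63, 17.45)
  ),
  interday = data.frame(
    level = c("LLQC", "LQC", "MQC", "HQC"),
    nominal = c(1, 3, 900, 2400),
    mean = c(1.03, 3.22, 886.99, 2365.33),
    sd = c(0.06, 0.20, 6.17, 17.61)
  )
)

# Independent weighted-least-squares oracle: explicit normal equations,
# never touching lm(). Returns slope, intercept, weighted r-squared, and the
# intercept standard error from the weighted covariance.
wls_oracle <- function(x, y, w) {
  A <- matrix(c(sum(w), sum(w * x), sum(w * x), sum(w * x^2)), 2, 2)
  b <- c(sum(w * y), sum(w * x * y))
  beta <- solve(A, b)
  e <- y - beta[1] - beta[2] * x
  ybar_w <- sum(w * y) / sum(w)
  sigma2 <- sum(w * e^2) / (length(x) - 2)
  covb <- sigma2 * solve(A)
  list(intercept = beta[1], slope = beta[2],
       r_squared = 1 - sum(w * e^2) / sum(w * (y - ybar_w)^2),
       intercept_sd = sqrt(covb[1, 1]))
}

# Absolute-difference comparison for values checked against a printed
# (rounded) figure, where relative tolerance is the wrong yardstick.
expect_close <- function(actual, expected, tol) {
  testthat::expect_lt(max(abs(actual - expected)), tol)
}

# QC table with exact values (zero noise, optional bias) for contract tests.
exact_qc <- function(bias = 0, levels = c(LLQC = 1, LQC = 3, MQC = 900, HQC = 2400),
                     days = 3, reps = 3) {
  grid <- expand.grid(replicate = seq_len(reps), day = seq_len(days),
                      level = names(levels), stringsAsFactors = FALSE)
  qc_table(grid$level, levels[grid$level], grid$day, grid$replicate,
           levels[grid$level] * (1 + bias))
}
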