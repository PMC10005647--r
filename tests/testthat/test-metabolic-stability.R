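test_that("percent remaining reproduces the published depletion percentages", {
  pr <- percent_remaining(depletion_tc())
  expect_equal(pr$pct_remaining[1], 100)
  expect_close(pr$pct_remaining[pr$time == 2.5], 91.44, 0.005)
  expect_close(pr$pct_remaining[pr$time == 30], 36.64, 0.005)
  expect_close(pr$pct_remaining[2:6], c(91.44, 78.25, 62.84, 52.74, 36.64),
               0.005)

  # replicates are averaged before the percentage is formed
  tc2 <- time_course(rep(c(0, 10), 2), c(90, 40, 110, 60), rep(1:2, each = 2))
  expect_equal(percent_remaining(tc2)$pct_remaining, c(100, 50))

  expect_error(percent_remaining(time_course(c(0, 5), c(0, 0))),
               class = "metstabr_validation_error")
})

test_that("the linear range is the longest r2-qualifying prefix anchored at zero", {
  pr <- percent_remaining(depletion_tc())
  rng <- select_linear_range(pr$time, pr$pct_remaining)
  expect_equal(rng$t_start, 0)
  expect_equal(rng$t_end, 30)
  expect_equal(rng$n_points, 6)
  expect_gte(rng$r_squared, 0.99)
  expect_true(rng$qualified)

  # a perfect exponential with no plateau keeps the full range
  t <- seq(0, 60, by = 10)
  X <- 100 * exp(-0.05 * t)
  full <- select_linear_range(t, X)
  expect_equal(full$t_end, 60)
  expect_equal(full$r_squared, 1, tolerance = 1e-12)

  # a flat curve has no qualifying prefix: fallback with a warning
  expect_warning(flat <- select_linear_range(t, rep(100, length(t))),
                 regexp = "falling back")
  expect_false(flat$qualified)

  # manual override is honored verbatim
  pin <- select_linear_range(pr$time, pr$pct_remaining, range_override = c(0, 20))
  expect_equal(pin$t_end, 20)

  expect_error(select_linear_range(c(0, 5, 10), c(100, 80, 60)),
               class = "metstabr_validation_error")
})

test_that("the ln-linear fit reproduces the published decay line", {
  pr <- percent_remaining(depletion_tc())
  dec <- fit_decay(pr$time, pr$pct_remaining, c(0, 30))
  expect_close(-dec$k, -0.0329, 1e-4)
  expect_close(dec$ln_intercept, 4.6097, 5e-4)
  expect_close(dec$r_squared, 0.998, 5e-4)

  # exact exponential: k and r2 recovered to machine precision
  t <- c(0, 2, 5, 9, 14)
  dec2 <- fit_decay(t, 100 * exp(-0.05 * t))
  expect_equal(dec2$k, 0.05, tolerance = 1e-12)
  expect_equal(dec2$r_squared, 1, tolerance = 1e-12)

  expect_error(fit_decay(c(0, 5, 10), c(100, 0, 10)), regexp = "t = 5",
               class = "metstabr_validation_error")
})

test_that("half-life and clearance scaling follow the unit identities", {
  expect_close(half_life(0.0329), 21.07, 0.005)
  expect_equal(half_life(log(2)), 1.0)
  expect_error(half_life(0), class = "metstabr_validation_error")

  cl <- intrinsic_clearance(21.07)
  expect_close(unname(cl["clint_per_kg"]), 38.48, 0.005)
  expect_equal(unname(cl["clint_per_kg"]),
               unname(cl["clint_per_mg"]) * 45 * 26 / 1000, tolerance = 1e-12)

  expect_equal(unname(intrinsic_clearance(0.693,
                                          scaling_factors(1, 1, 1))["clint_per_kg"]),
               1.0)
  # exact-ln2 variant available
  expect_equal(unname(intrinsic_clearance(log(2), scaling_factors(1, 1, 1),
                                          decay_constant = log(2))["clint_per_kg"]),
               1.0)
  expect_error(intrinsic_clearance(0), class = "metstabr_validation_error")
  expect_error(scaling_factors(ml_per_mg = -1), class = "metstabr_validation_error")
})

test_that("clearance classification bands with boundaries in the middle class", {
  expect_equal(classify_clearance(0), "low")
  expect_equal(classify_clearance(1000), "high")
  expect_equal(classify_clearance(32.89), "intermediate")
  expect_equal(classify_clearance(8.6), "intermediate")
  expect_equal(classify_clearance(47), "intermediate")
  expect_equal(classify_clearance(8.59), "low")
  expect_equal(classify_clearance(47.01), "high")
  expect_error(clearance_bands(50, 10), class = "metstabr_validation_error")
})

test_that("the composed pipeline reproduces the published stability summary", {
  res <- run_metstab(depletion_tc())
  expect_equal(unname(res$linear_range), c(0, 30))
  expect_close(res$k, 0.0329, 1e-4)
  expect_close(res$t_half, 21.07, 0.05)
  expect_close(res$clint_per_kg, 38.48, 0.1)
  expect_equal(res$clearance_class, "intermediate")

  # a constant time course raises a structured no-decay error downstream
  flat <- time_course(c(0, 10, 20, 30), rep(100, 4))
  expect_error(suppressWarnings(run_metstab(flat)),
               regexp = "no measurable decay",
               class = "metstabr_validation_error")
})

test_that("the pipeline is scale-invariant and monotone in the decay rate", {
  tc <- simulate_timecourse(sim_config(seed = 5), noise_cv = 0)$tc
  base <- run_metstab(tc, range_override = c(0, 30))
  scaled <- run_metstab(time_course(tc$time, tc$measured_conc * 3.14,
                                    tc$replicate),
                        range_override = c(0, 30))
  expect_equal(scaled$percent_remaining$pct_remaining,
               base$percent_remaining$pct_remaining, tolerance = 1e-12)
  expect_equal(scaled$k, base$k, tolerance = 1e-12)
  expect_equal(scaled$clint_per_kg, base$clint_per_kg, tolerance = 1e-12)

  ks <- c(0.01, 0.03, 0.09)
  res <- lapply(ks, function(k) {
    run_metstab(simulate_timecourse(sim_config(seed = 1, k_true = k,
                                               plateau_pct = 0),
                                    noise_cv = 0)$tc,
                range_override = c(0, 30))
  })
  t_halves <- vapply(res, `[[`, 0, "t_half")
  clints <- vapply(res, `[[`, 0, "clint_per_kg")
  expect_true(all(diff(t_halves) < 0))
  expect_true(all(diff(clints) > 0))
})

test_that("zero-noise simulated time courses return the generator's rate exactly", {
  for (plateau in c(0, 26)) {
    sim <- simulate_timecourse(sim_config(seed = 2, plateau_pct = plateau),
                               noise_cv = 0)
    res <- run_metstab(sim$tc, range_override = c(0, 30))
    expect_equal(res$k, sim$truth$k_eff, tolerance = 1e-9)
    expect_equal(res$t_half, sim$truth$t_half_eff, tolerance = 1e-6)
  }
})
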