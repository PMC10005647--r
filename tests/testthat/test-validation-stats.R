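test_that("RSD and RE reproduce the published QC summary cells", {
  # published cells carry mean/SD; recomputation from those is only stable
  # against rounding at the MQC/HQC levels (at the low levels, rounding of a
  # two-decimal SD alone moves the RSD by several tenths of a percent)
  for (scope in names(published_qc_cells)) {
    cells <- published_qc_cells[[scope]][3:4, ]  # MQC, HQC
    expect_close(100 * cells$sd / cells$mean,
                 switch(scope, intraday = c(0.29, 0.73),
                        interday = c(0.70, 0.74)),
                 0.05)
    expect_close(100 * (cells$mean - cells$nominal) / cells$nominal,
                 switch(scope, intraday = c(-0.59, -0.25),
                        interday = c(-1.45, -1.44)),
                 0.05)
  }
  # the package functions give the same numbers from replicate values
  # constructed to have the published mean and SD
  d <- 17.61 / sqrt(2)
  vals <- c(2365.33 - d, 2365.33 + d)  # mean 2365.33, sd 17.61
  expect_close(precision_rsd(vals), 0.74, 0.01)
  d2 <- 17.45 / sqrt(2)
  expect_close(precision_rsd(c(2394.09 - d2, 2394.09 + d2)), 0.73, 0.01)
  expect_close(accuracy_re(c(886.99, 886.99), 900), -1.45, 0.01)
  expect_close(accuracy_re(c(2394.09, 2394.09), 2400), -0.25, 0.01)
})

test_that("precision and accuracy have the documented invariances", {
  set.seed(11)
  vals <- rlnorm(8, log(100), 0.1)
  expect_equal(precision_rsd(vals * 7.3), precision_rsd(vals), tolerance = 1e-12)
  expect_equal(accuracy_re(vals * 7.3, 100 * 7.3), accuracy_re(vals, 100),
               tolerance = 1e-12)
  expect_equal(precision_rsd(rep(5, 4)), 0)
  expect_equal(accuracy_re(rep(5, 4), 5), 0)
  expect_error(precision_rsd(3), class = "metstabr_validation_error")
  expect_error(accuracy_re(c(1, 2), 0), class = "metstabr_validation_error")
})

test_that("recovery, matrix effect, and IS normalization behave as ratios of means", {
  set.seed(4)
  x <- rlnorm(6, log(1000), 0.05)
  expect_equal(recovery_pct(x, x), 100)
  expect_equal(matrix_effect(x, x), 100)
  expect_close(is_normalized_me(101.74, 102.24), 0.995, 5e-4)
  expect_equal(is_normalized_me(88, 88), 1.0)
  expect_equal(is_normalized_me(2 * 88, 88), 2.0)
  expect_close(mean(published_recoveries), 101.33, 0.01)
  expect_error(matrix_effect(x, numeric(0)), class = "metstabr_validation_error")
  expect_error(is_normalized_me(100, 0), class = "metstabr_validation_error")
})

test_that("synthetic recovery and matrix effect are recovered over seeds", {
  me_hat <- vapply(1:100, function(s) {
    matrix_effect(simulate_matrix_effect_sets(
      sim_config(seed = s, me_true = 0.9))$me_set)
  }, 0)
  expect_equal(mean(me_hat), 90, tolerance = 1)
  # recovery uses the same pair structure with recovery_true as the scale
  rec_hat <- vapply(1:100, function(s) {
    st <- simulate_matrix_effect_sets(sim_config(seed = s, me_true = 0.85))$me_set
    recovery_pct(st$set1_values, st$set2_values)
  }, 0)
  expect_equal(mean(rec_hat), 85, tolerance = 1)
})

test_that("stability cells apply the tolerance window to the mean percent", {
  ref <- rep(100, 5)
  cell <- stability_pct(ref, ref)
  expect_equal(cell$mean_pct, 100)
  expect_true(cell$pass)

  published <- stability_pct(c(98.8), 100, condition = "freeze_thaw",
                             level_label = "LQC")
  expect_true(published$pass)

  expect_false(stability_pct(80, 100)$pass)
  expect_true(stability_pct(85, 100)$pass)  # boundary |85 - 100| <= 15
  expect_error(stability_pct(c(1, 2), 0), class = "metstabr_validation_error")
})

test_that("carryover passes at or below the limits and fails above", {
  expect_true(carryover_check(0, 100, 0, 1000)$pass)
  expect_false(carryover_check(25, 100, 0, 1000)$pass)
  expect_true(carryover_check(20, 100, 50, 1000)$pass)   # exactly 20% and 5%
  expect_false(carryover_check(0, 100, 51, 1000)$pass)   # IS channel fails
  expect_error(carryover_check(1, 0, 1, 1), class = "metstabr_validation_error")
})

test_that("the precision/accuracy grid pools days correctly and is exact at zero noise", {
  tab <- precision_accuracy_table(exact_qc())
  expect_equal(nrow(tab), 8)
  expect_equal(tab$re_pct, rep(0, 8))
  expect_equal(tab$rsd_pct, rep(0, 8))
  expect_equal(tab$recovery_pct, rep(100, 8))
  expect_equal(tab$n[tab$scope == "intraday"], rep(3, 4))
  expect_equal(tab$n[tab$scope == "interday"], rep(9, 4))
  # levels ordered by nominal concentration
  expect_equal(unique(tab$level_label), c("LLQC", "LQC", "MQC", "HQC"))

  biased <- precision_accuracy_table(exact_qc(bias = 0.05))
  expect_equal(biased$re_pct, rep(5, 8), tolerance = 1e-12)
  expect_equal(biased$recovery_pct, biased$re_pct + 100)

  one_rep <- qc_table("LQC", 3, 1, 1, 3.1)
  expect_error(precision_accuracy_table(one_rep),
               regexp = "fewer than 2", class = "metstabr_validation_error")
})

test_that("simulated QC tables with known bias recover RE over seeds", {
  re_hat <- vapply(1:100, function(s) {
    tab <- precision_accuracy_table(simulate_qc(sim_config(seed = s), bias = 0.05)$qc)
    mean(tab$re_pct[tab$scope == "interday"])
  }, 0)
  expect_equal(mean(re_hat), 5, tolerance = 0.5)
})
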