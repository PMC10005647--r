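# FDA-style bioanalytical validation statistics: precision, accuracy,
# recovery, matrix effect, carryover, stability. Sample (n-1) SD throughout.

#' Precision as percent relative standard deviation
#'
#' `RSD% = 100 * sd / mean` over replicate concentrations; scale-invariant.
#'
#' @param values Replicate measurements (n >= 2, non-zero mean).
#' @return RSD in percent.
#' @export
precision_rsd <- function(values) {
  if (length(values) < 2) validation_error("RSD requires at least 2 replicates")
  m <- mean(values)
  if (m == 0) validation_error("RSD undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Accuracy as percent relative error
#'
#' `RE% = 100 * (mean - nominal) / nominal`.
#'
#' @param values Replicate measurements.
#' @param nominal Nominal (proposed) concentration, > 0.
#' @return RE in percent (signed).
#' @export
accuracy_re <- function(values, nominal) {
  if (!is.finite(nominal) || nominal <= 0) {
    validation_error("nominal concentration must be > 0")
  }
  100 * (mean(values) - nominal) / nominal
}

#' Extraction recovery
#'
#' Ratio of mean response extracted from matrix (B) to mean response in neat
#' solvent (A), as a percentage: `100 * mean(B) / mean(A)`.
#'
#' @param matrix_values Responses after extraction from matrix (B).
#' @param neat_values Responses prepared in neat solvent (A).
#' @return Recovery in percent.
#' @export
recovery_pct <- function(matrix_values, neat_values) {
  if (length(matrix_values) == 0 || length(neat_values) == 0) {
    validation_error("both groups must be non-empty")
  }
  a <- mean(neat_values)
  if (a == 0) validation_error("zero neat-solvent mean")
  100 * mean(matrix_values) / a
}

#' Matrix effect
#'
#' `ME% = 100 * mean(set 1) / mean(set 2)` where set 1 was prepared in
#' biological matrix and set 2 in neat solvent. 100% means the matrix does
#' not alter ionization.
#'
#' @param set1 Responses in matrix, or a [matrix_effect_set()].
#' @param set2 Responses in neat solvent (ignored when `set1` is a
#'   [matrix_effect_set()]).
#' @return ME in percent.
#' @export
matrix_effect <- function(set1, set2 = NULL) {
  if (inherits(set1, "matrix_effect_set")) {
    set2 <- set1$set2_values
    set1 <- set1$set1_values
  }
  if (length(set1) == 0 || length(set2) == 0) {
    validation_error("both matrix-effect sets must be non-empty")
  }
  d <- mean(set2)
  if (d == 0) validation_error("zero neat-set mean")
  100 * mean(set1) / d
}

#' IS-normalized matrix effect
#'
#' Analyte matrix effect divided by the internal standard's matrix effect, a
#' dimensionless factor whose ideal value is 1.
#'
#' @param me_analyte Analyte ME in percent.
#' @param me_is Internal-standard ME in percent (non-zero).
#' @return The normalized matrix factor.
#' @export
is_normalized_me <- function(me_analyte, me_is) {
  if (me_is == 0) validation_error("IS matrix effect must be non-zero")
  me_analyte / me_is
}

#' Stability of stored samples
#'
#' Expresses stored-sample responses as a percentage of a fresh reference
#' (either replicate fresh values or a nominal concentration) and applies
#' the ±`tolerance_pct` acceptance window to the mean.
#'
#' @param stored_values Measurements after storage/stress.
#' @param fresh_reference Fresh replicate values, or a single nominal value.
#' @param tolerance_pct Acceptance half-width in percent (default 15).
#' @param condition Storage condition label (`"freeze_thaw"`, `"short_term"`,
#'   `"long_term"`, `"autosampler"`, or free text).
#' @param level_label QC level label for reporting.
#' @return A one-row data frame of class `"stability_cell"` with `mean_pct`,
#'   `sd_pct`, and `pass`.
#' @export
stability_pct <- function(stored_values, fresh_reference, tolerance_pct = 15,
                          condition = "short_term", level_label = NA_character_) {
  if (length(stored_values) == 0 || length(fresh_reference) == 0) {
    validation_error("stored and reference values must be non-empty")
  }
  ref <- mean(fresh_reference)
  if (ref == 0) validation_error("zero fresh reference")
  pct <- 100 * stored_values / ref
  out <- data.frame(
    condition = condition, level_label = level_label,
    mean_pct = mean(pct),
    sd_pct = if (length(pct) > 1) stats::sd(pct) else 0,
    pass = abs(mean(pct) - 100) <= tolerance_pct
  )
  class(out) <- c("stability_cell", "data.frame")
  out
}

#' Carryover check on a blank after a high sample
#'
#' Residual analyte signal in a blank injected after a high-concentration
#' sample must not exceed `analyte_limit_pct` of the LLOQ response, and
#' residual IS signal must not exceed `is_limit_pct` of the working IS
#' response. Boundary values pass (<=).
#'
#' @param blank_after_high_area Analyte area in the post-high blank.
#' @param lloq_area Analyte area at the LLOQ (> 0).
#' @param is_blank_area IS area in the blank.
#' @param is_area Working IS area (> 0).
#' @param analyte_limit_pct Analyte limit as percent of LLOQ (default 20).
#' @param is_limit_pct IS limit as percent of IS response (default 5).
#' @return A list with `pass`, per-channel percentages, and the limits used.
#' @export
carryover_check <- function(blank_after_high_area, lloq_area,
                            is_blank_area, is_area,
                            analyte_limit_pct = 20, is_limit_pct = 5) {
  if (lloq_area <= 0 || is_area <= 0) {
    validation_error("LLOQ and IS reference areas must be > 0")
  }
  analyte_pct <- 100 * blank_after_high_area / lloq_area
  is_pct <- 100 * is_blank_area / is_area
  list(
    pass = analyte_pct <= analyte_limit_pct && is_pct <= is_limit_pct,
    analyte_pct = analyte_pct, is_pct = is_pct,
    analyte_limit_pct = analyte_limit_pct, is_limit_pct = is_limit_pct
  )
}

#' Precision/accuracy grid from a QC table
#'
#' Builds the intraday/interday precision and accuracy table: intraday cells
#' pool the replicates of one day per level (day 1 unless `intraday_day` is
#' given); interday cells pool all replicates across days. Each cell carries
#' n, mean, SD, RSD%, RE%, and recovery% (`RE% + 100`).
#'
#' @param qc A [qc_table()].
#' @param intraday_day Day used for the intraday scope (default: first day).
#' @return A data frame with one row per (level, scope) cell, ordered by
#'   nominal concentration.
#' @export
precision_accuracy_table <- function(qc, intraday_day = NULL) {
  if (is.null(intraday_day)) intraday_day <- min(qc$day)
  levels_in_order <- unique(qc$level[order(qc$nominal_conc)])
  cell <- function(values, level, nominal, scope) {
    if (length(values) < 2) {
      validation_error(sprintf("level '%s' (%s) has fewer than 2 replicates",
                               level, scope))
    }
    re <- accuracy_re(values, nominal)
    data.frame(
      level_label = level, scope = scope, n = length(values),
      mean = mean(values), sd = stats::sd(values),
      rsd_pct = precision_rsd(values), re_pct = re,
      recovery_pct = re + 100
    )
  }
  rows <- lapply(levels_in_order, function(lv) {
    sub <- qc[qc$level == lv, ]
    nominal <- sub$nominal_conc[1]
    rbind(
      cell(sub$measured_conc[sub$day == intraday_day], lv, nominal, "intraday"),
      cell(sub$measured_conc, lv, nominal, "interday")
    )
  })
  do.call(rbind, rows)
}
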