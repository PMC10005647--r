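# Shared domain containers. All concentrations are carried in ng/mL and all
# times in minutes; unit conversion happens only inside the clearance scaling.

validation_error <- function(msg, row = NULL) {
  if (!is.null(row)) msg <- sprintf("%s (row %s)", msg, paste(row, collapse = ", "))
  stop(errorCondition(msg, class = c("metstabr_validation_error", "error")))
}

check_numeric <- function(x, name, rows = NULL) {
  x_num <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(x_num) & !is.na(x))
  if (length(bad) > 0) {
    validation_error(sprintf("non-numeric value in column '%s'", name), bad)
  }
  if (anyNA(x_num)) {
    validation_error(sprintf("missing value in column '%s'", name), which(is.na(x_num)))
  }
  x_num
}

#' Calibration standard set
#'
#' A set of calibration standards: nominal concentrations with either raw
#' analyte / internal-standard (IS) peak areas or directly supplied response
#' ratios. When both areas are present the response ratio is recomputed as
#' `analyte_area / is_area` and overrides any supplied ratio column, so the
#' areas are the single source of truth. When only ratios are supplied, the
#' area columns are absent, never fabricated.
#'
#' @param nominal_conc Nominal concentrations in ng/mL (all > 0).
#' @param analyte_area Analyte peak areas (arbitrary units, >= 0), or `NULL`.
#' @param is_area Internal-standard peak areas (> 0), or `NULL`. Required
#'   whenever `analyte_area` is given.
#' @param response_ratio Dimensionless analyte/IS response ratios; ignored
#'   when areas are present, required otherwise.
#' @return A data frame of class `"calibration_set"`.
#' @export
calibration_set <- function(nominal_conc, analyte_area = NULL, is_area = NULL,
                            response_ratio = NULL) {
  nominal_conc <- check_numeric(nominal_conc, "nominal_conc")
  if (any(nominal_conc <= 0)) {
    validation_error("nominal_conc must be > 0", which(nominal_conc <= 0))
  }
  has_areas <- !is.null(analyte_area) || !is.null(is_area)
  if (has_areas) {
    if (is.null(analyte_area) || is.null(is_area)) {
      validation_error("analyte_area and is_area must be supplied together")
    }
    analyte_area <- check_numeric(analyte_area, "analyte_area")
    is_area <- check_numeric(is_area, "is_area")
    if (any(analyte_area < 0)) {
      validation_error("analyte_area must be >= 0", which(analyte_area < 0))
    }
    if (any(is_area <= 0)) {
      validation_error("is_area must be > 0", which(is_area <= 0))
    }
    out <- data.frame(
      nominal_conc = nominal_conc,
      analyte_area = analyte_area,
      is_area = is_area,
      response_ratio = analyte_area / is_area
    )
  } else {
    if (is.null(response_ratio)) {
      validation_error("either peak areas or response_ratio must be supplied")
    }
    out <- data.frame(
      nominal_conc = nominal_conc,
      response_ratio = check_numeric(response_ratio, "response_ratio")
    )
  }
  class(out) <- c("calibration_set", "data.frame")
  out
}

#' Quality-control replicate table
#'
#' Back-calculated QC concentrations keyed by level, day, and replicate, the
#' input to the precision/accuracy grid. Levels follow the usual LLQC / LQC /
#' MQC / HQC naming but any labels are accepted; the nominal concentration
#' must be constant within a level and every `(level, day, replicate)` key
#' must be unique.
#'
#' @param level Character level labels (e.g. "LLQC", "HQC").
#' @param nominal_conc Nominal concentration in ng/mL, constant per level.
#' @param day Day index (>= 1).
#' @param replicate Replicate index (>= 1).
#' @param measured_conc Back-calculated concentration in ng/mL.
#' @return A data frame of class `"qc_table"`.
#' @export
qc_table <- function(level, nominal_conc, day, replicate, measured_conc) {
  out <- data.frame(
    level = as.character(level),
    nominal_conc = check_numeric(nominal_conc, "nominal_conc"),
    day = check_numeric(day, "day"),
    replicate = check_numeric(replicate, "replicate"),
    measured_conc = check_numeric(measured_conc, "measured_conc")
  )
  if (any(out$nominal_conc <= 0)) {
    validation_error("nominal_conc must be > 0", which(out$nominal_conc <= 0))
  }
  if (any(out$day < 1) || any(out$replicate < 1)) {
    validation_error("day and replicate indices must be >= 1",
                     which(out$day < 1 | out$replicate < 1))
  }
  key <- paste(out$level, out$day, out$replicate)
  if (anyDuplicated(key)) {
    validation_error("duplicate (level, day, replicate) key",
                     which(duplicated(key)))
  }
  per_level <- tapply(out$nominal_conc, out$level, function(x) length(unique(x)))
  if (any(per_level > 1)) {
    validation_error(sprintf("nominal_conc not constant within level '%s'",
                             names(per_level)[per_level > 1][1]))
  }
  class(out) <- c("qc_table", "data.frame")
  out
}

#' Matrix-effect sample pair
#'
#' Matched responses for one analyte measured in biological matrix (set 1)
#' and in neat solvent (set 2), the input to the matrix-effect ratio.
#'
#' @param set1_values Peak areas or ratios measured in matrix (non-empty).
#' @param set2_values Matched values in neat solvent (non-empty).
#' @param analyte_label Name of the analyte the pair belongs to.
#' @return A list of class `"matrix_effect_set"`.
#' @export
matrix_effect_set <- function(set1_values, set2_values, analyte_label = "analyte") {
  set1_values <- check_numeric(set1_values, "set1_values")
  set2_values <- check_numeric(set2_values, "set2_values")
  if (length(set1_values) == 0 || length(set2_values) == 0) {
    validation_error("both matrix-effect sets must be non-empty")
  }
  structure(
    list(set1_values = set1_values, set2_values = set2_values,
         analyte_label = as.character(analyte_label)),
    class = "matrix_effect_set"
  )
}

#' Incubation time course
#'
#' Measured concentrations over incubation time for one substrate-depletion
#' experiment. Must contain time 0 (the 100% reference) unless
#' `zero_time_required = FALSE`; times must be strictly increasing within a
#' replicate and concentrations non-negative.
#'
#' @param time Incubation time in minutes (>= 0).
#' @param measured_conc Measured concentration in ng/mL (>= 0).
#' @param replicate Replicate index.
#' @param zero_time_required Require a time-0 observation (default `TRUE`).
#' @return A data frame of class `"time_course"`.
#' @export
time_course <- function(time, measured_conc, replicate = 1L,
                        zero_time_required = TRUE) {
  out <- data.frame(
    time = check_numeric(time, "time"),
    measured_conc = check_numeric(measured_conc, "measured_conc"),
    replicate = check_numeric(replicate, "replicate")
  )
  if (any(out$time < 0)) {
    validation_error("time must be >= 0", which(out$time < 0))
  }
  if (any(out$measured_conc < 0)) {
    validation_error("measured_conc must be >= 0", which(out$measured_conc < 0))
  }
  if (zero_time_required && !any(out$time == 0)) {
    validation_error("time course must contain time 0")
  }
  for (r in unique(out$replicate)) {
    tt <- out$time[out$replicate == r]
    if (any(diff(tt) <= 0)) {
      validation_error(sprintf("times not strictly increasing in replicate %s", r))
    }
  }
  attr(out, "zero_time_required") <- zero_time_required
  class(out) <- c("time_course", "data.frame")
  out
}

#' Physiological scaling factors for intrinsic clearance
#'
#' Factors that scale the in vitro elimination rate to whole-body intrinsic
#' clearance: incubation volume per mg of microsomal protein, microsomal
#' protein content of liver, and liver weight per kg body weight. Defaults
#' are the conventional human values (1 mL incubation per mg protein for a
#' 1 mg/mL incubation, 45 mg microsomal protein per g liver, 26 g liver per
#' kg body weight).
#'
#' @param ml_per_mg mL incubation per mg microsomal protein.
#' @param mg_per_g_liver mg microsomal protein per g liver.
#' @param g_liver_per_kg g liver per kg body weight.
#' @return A list of class `"scaling_factors"`.
#' @export
scaling_factors <- function(ml_per_mg = 1, mg_per_g_liver = 45,
                            g_liver_per_kg = 26) {
  vals <- c(ml_per_mg = ml_per_mg, mg_per_g_liver = mg_per_g_liver,
            g_liver_per_kg = g_liver_per_kg)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    validation_error("all scaling factors must be strictly positive")
  }
  structure(as.list(vals), class = "scaling_factors")
}

#' Clearance classification bands
#'
#' Intrinsic-clearance cut points (in uL/min/mg microsomal protein) that band
#' a compound into low / intermediate / high clearance. Defaults follow the
#' McNaney scoring convention (low below 8.6, high above 47).
#'
#' @param low_max Upper bound of the low-clearance band, uL/min/mg.
#' @param high_min Lower bound of the high-clearance band, uL/min/mg.
#' @return A list of class `"clearance_bands"`.
#' @export
clearance_bands <- function(low_max = 8.6, high_min = 47) {
  if (!is.finite(low_max) || !is.finite(high_min) || low_max >= high_min) {
    validation_error("clearance bands require low_max < high_min")
  }
  structure(list(low_max = low_max, high_min = high_min),
            class = "clearance_bands")
}

#' Per-site metabolic lability set
#'
#' Lability rate constants for individual atom sites plus the water-formation
#' rate constant, the inputs to the composite site lability (CSL) score. The
#' per-site constants are user-supplied (e.g. exported from an upstream P450
#' regioselectivity predictor); this package only aggregates them.
#'
#' @param site_ks Named non-negative numeric vector of per-site rate
#'   constants (names are atom labels).
#' @param k_w Water-formation rate constant (>= 0).
#' @return A list of class `"site_lability_set"`.
#' @export
site_lability_set <- function(site_ks, k_w) {
  labels <- names(site_ks)
  site_ks <- check_numeric(site_ks, "site_ks")
  if (length(site_ks) == 0) validation_error("at least one site is required")
  names(site_ks) <- if (is.null(labels) || any(!nzchar(labels))) {
    paste0("site", seq_along(site_ks))
  } else {
    labels
  }
  k_w <- check_numeric(k_w, "k_w")
  if (any(site_ks < 0) || k_w < 0) {
    validation_error("lability rate constants must be >= 0")
  }
  if (sum(site_ks) + k_w == 0) {
    validation_error("sum of site constants and k_w must be positive")
  }
  structure(list(site_ks = site_ks, k_w = k_w), class = "site_lability_set")
}
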