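# CSV readers/writers for the exchange schemas and the JSON run report.
# CSV is the canonical format: header row, period decimal separator, UTF-8.

table_schemas <- list(
  calibration = c("nominal_conc", "analyte_area", "is_area"),
  qc = c("level", "nominal_conc", "day", "replicate", "measured_conc"),
  matrix_effect = c("analyte", "set", "value"),
  timecourse = c("time_min", "conc_ng_ml", "replicate"),
  stability = c("condition", "level", "stored", "fresh")
)

#' Read a typed table from CSV
#'
#' Reads one of the documented CSV schemas and returns the corresponding
#' validated domain object. Row order is preserved and units are taken as
#' documented (minutes, ng/mL). Schemas:
#'
#' * `calibration`: `nominal_conc, analyte_area, is_area` (or
#'   `nominal_conc, response_ratio` when raw areas are unavailable) ->
#'   [calibration_set()]
#' * `qc`: `level, nominal_conc, day, replicate, measured_conc` ->
#'   [qc_table()]
#' * `matrix_effect`: `analyte, set, value` with `set` in \{1, 2\} -> a named
#'   list of [matrix_effect_set()], one per analyte
#' * `timecourse`: `time_min, conc_ng_ml, replicate` -> [time_course()]
#' * `stability`: `condition, level, stored, fresh` -> a validated data frame
#'   of stored/fresh response pairs
#'
#' Validation failures (missing column, non-numeric cell, negative
#' concentration, duplicate QC key) raise a classed error naming the row.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"calibration"`, `"qc"`, `"matrix_effect"`,
#'   `"timecourse"`, `"stability"`.
#' @return The validated domain object for the schema.
#' @export
read_table <- function(path, schema = names(table_schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) validation_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")

  need <- table_schemas[[schema]]
  if (schema == "calibration" && !all(c("analyte_area", "is_area") %in% names(df))) {
    # ratio-only variant is allowed; a lone area column is not
    if (any(c("analyte_area", "is_area") %in% names(df))) {
      missing_col <- setdiff(c("analyte_area", "is_area"), names(df))
      validation_error(sprintf("missing column '%s' (peak areas must come in pairs)",
                               missing_col[1]))
    }
    need <- c("nominal_conc", "response_ratio")
  }
  absent <- setdiff(need, names(df))
  if (length(absent) > 0) {
    validation_error(sprintf("missing column '%s' for schema '%s'", absent[1], schema))
  }

  switch(schema,
    calibration = {
      if ("analyte_area" %in% names(df)) {
        calibration_set(df$nominal_conc, df$analyte_area, df$is_area)
      } else {
        calibration_set(df$nominal_conc, response_ratio = df$response_ratio)
      }
    },
    qc = qc_table(df$level, df$nominal_conc, df$day, df$replicate, df$measured_conc),
    matrix_effect = {
      df$value <- check_numeric(df$value, "value")
      df$set <- check_numeric(df$set, "set")
      if (!all(df$set %in% c(1, 2))) {
        validation_error("column 'set' must contain only 1 (matrix) or 2 (neat)",
                         which(!df$set %in% c(1, 2)))
      }
      sets <- lapply(split(df, df$analyte), function(d) {
        matrix_effect_set(d$value[d$set == 1], d$value[d$set == 2],
                          analyte_label = d$analyte[1])
      })
      sets[unique(df$analyte)]
    },
    timecourse = time_course(df$time_min, df$conc_ng_ml, df$replicate),
    stability = {
      df$stored <- check_numeric(df$stored, "stored")
      df$fresh <- check_numeric(df$fresh, "fresh")
      if (any(df$stored < 0) || any(df$fresh < 0)) {
        validation_error("stability responses must be >= 0",
                         which(df$stored < 0 | df$fresh < 0))
      }
      df
    }
  )
}

#' Write a typed table to CSV
#'
#' Inverse of [read_table()]: writes a domain object using the documented
#' column names so that `read_table(write_table(x))` round-trips losslessly.
#'
#' @param x A [calibration_set()], [qc_table()], [time_course()], a named
#'   list of [matrix_effect_set()], or a stability data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  df <- if (inherits(x, "time_course")) {
    data.frame(time_min = x$time, conc_ng_ml = x$measured_conc, replicate = x$replicate)
  } else if (inherits(x, "matrix_effect_set") ||
             (is.list(x) && !is.data.frame(x) && all(vapply(x, inherits, TRUE, "matrix_effect_set")))) {
    sets <- if (inherits(x, "matrix_effect_set")) list(x) else x
    do.call(rbind, lapply(sets, function(s) {
      data.frame(
        analyte = s$analyte_label,
        set = rep(c(1, 2), c(length(s$set1_values), length(s$set2_values))),
        value = c(s$set1_values, s$set2_values)
      )
    }))
  } else if (is.data.frame(x)) {
    as.data.frame(x)
  } else {
    validation_error("unsupported object for write_table")
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read MRM acquisition metadata
#'
#' Loads a YAML block of MRM tuning metadata (precursor/product m/z, cone
#' voltage, collision energy, retention time, ...). The content is carried
#' verbatim into reports for provenance and never interpreted numerically.
#'
#' @param path Path to a YAML file.
#' @return The parsed YAML as a list.
#' @export
read_mrm_metadata <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("file not found: %s", path))
  yaml::read_yaml(path)
}

report_section_order <- c("config", "provenance", "mrm_metadata", "simulation",
                          "calibration", "validation", "metstab", "csl")

#' Write a consolidated run report
#'
#' Serialises stage outputs into one machine-readable JSON document with a
#' deterministic section order, echoing the configuration and input
#' provenance so any report is reproducible from what it records. Numeric
#' values are written at full precision.
#'
#' @param results Named list of stage outputs; at least one must be non-NULL.
#'   Recognised section names come first, in fixed order.
#' @param path Output path for the JSON document.
#' @param config Optional configuration list echoed under `config`.
#' @param provenance Optional list describing input files/rows.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, config = list(), provenance = list()) {
  if (length(results) == 0 || all(vapply(results, is.null, TRUE))) {
    validation_error("report requires at least one stage output")
  }
  doc <- c(list(config = config, provenance = provenance), results)
  doc <- doc[!vapply(doc, is.null, TRUE)]
  known <- intersect(report_section_order, names(doc))
  doc <- doc[c(known, setdiff(names(doc), known))]
  doc <- rapply(doc, unclass, how = "replace")
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) validation_error(sprintf("cannot write report to %s", path))
  invisible(path)
}

#' Read back a run report
#'
#' @param path Path to a JSON report produced by [write_report()].
#' @return The report as a list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
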