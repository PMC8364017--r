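## File interfaces: program-record CSV, survey YAML, calibration-report
## JSON, trajectory and sensitivity CSV. All tables use the canonical
## state ordering.

.RECORD_COLUMNS <- c("program", "month", "admissions", "enrolled", "cured",
                     "defaulted", "non_response", "referred_tsfp",
                     "referred_otp", "referred_tfc", "died")

#' Validate a program-records table
#'
#' Checks column presence, program labels, non-negativity and the
#' outcomes-within-enrolment constraint, with errors naming the offending
#' row and field.
#'
#' @param records Data frame of monthly program records.
#' @return The validated data frame (columns in canonical order),
#'   invisibly usable downstream.
#' @export
validate_program_records <- function(records) {
  records <- as.data.frame(records)
  miss <- setdiff(.RECORD_COLUMNS, names(records))
  if (length(miss)) {
    stop("program records missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad_prog <- !records$program %in% .PROGRAMS
  if (any(bad_prog)) {
    stop("row ", which(bad_prog)[1L], ", field 'program': got '",
         records$program[which(bad_prog)[1L]], "', expected one of ",
         paste(.PROGRAMS, collapse = ", "), call. = FALSE)
  }
  count_cols <- setdiff(.RECORD_COLUMNS, "program")
  for (col in count_cols) {
    v <- records[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      bad <- which(!is.numeric(v) | !is.finite(v) | v < 0)[1L]
      stop("row ", bad, ", field '", col,
           "': must be a non-negative number", call. = FALSE)
    }
  }
  outcome_cols <- c("cured", "defaulted", "non_response", "referred_tsfp",
                    "referred_otp", "referred_tfc", "died")
  tot <- rowSums(records[outcome_cols])
  if (any(tot > records$enrolled)) {
    bad <- which(tot > records$enrolled)[1L]
    stop("row ", bad, ", field 'enrolled': outcome counts (", tot[bad],
         ") exceed enrolment (", records$enrolled[bad], ")", call. = FALSE)
  }
  records[.RECORD_COLUMNS]
}

#' Read or write monthly program records as CSV
#'
#' @param path File path.
#' @return \code{read_program_records} returns the validated data frame.
#' @export
read_program_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validate_program_records(utils::read.csv(path))
}

#' @rdname read_program_records
#' @param records Data frame of monthly program records.
#' @export
write_program_records <- function(records, path) {
  utils::write.csv(validate_program_records(records), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read survey summaries from YAML
#'
#' Expects a top-level \code{surveys:} list, each entry carrying
#' \code{region}, \code{under5_population}, \code{moderate_prevalence},
#' \code{severe_prevalence}, \code{under5_mortality_monthly} and
#' \code{survey_month}.
#'
#' @param path YAML file path.
#' @return List of \code{\link{survey_summary}}.
#' @export
read_surveys <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  entries <- doc$surveys %||% doc
  if (!length(entries)) stop("no surveys found in ", path, call. = FALSE)
  lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    need <- c("region", "under5_population", "moderate_prevalence",
              "severe_prevalence", "under5_mortality_monthly",
              "survey_month")
    miss <- setdiff(need, names(e))
    if (length(miss)) {
      stop("survey entry ", i, " missing field(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    do.call(survey_summary, e[need])
  })
}

#' Write survey summaries to YAML
#'
#' @param surveys List of \code{\link{survey_summary}}.
#' @param path Output path.
#' @export
write_surveys <- function(surveys, path) {
  if (inherits(surveys, "survey_summary")) surveys <- list(surveys)
  yaml::write_yaml(list(surveys = lapply(surveys, unclass)), path)
  invisible(path)
}

#' Calibration report JSON round trip
#'
#' Serialises a \code{calibration_result} (without its trajectory) to JSON
#' at full precision and reads it back losslessly.
#'
#' @param result A \code{calibration_result}.
#' @param path Output path.
#' @export
write_calibration_json <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  fields <- result[c("tier", "probability", "annual_incident_cases",
                     "baseline_prevalence", "k",
                     "mean_episode_duration_months", "achieved_prevalence",
                     "target_prevalence", "target_month", "iterations")]
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a trajectory as a per-month census CSV
#'
#' @param trajectory A \code{wasting_trajectory}.
#' @param path Output path.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "wasting_trajectory"))
  df <- data.frame(month = 0:trajectory$horizon, trajectory$counts,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write sensitivity results as long-format CSV plus a JSON ranking
#'
#' @param sensitivity Result of \code{\link{run_sensitivity}}.
#' @param csv_path Long-format CSV destination.
#' @param json_path Optional ranking JSON destination.
#' @export
write_sensitivity_report <- function(sensitivity, csv_path,
                                     json_path = NULL) {
  utils::write.csv(sensitivity$sweeps, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(sensitivity$ranking, json_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  invisible(csv_path)
}
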