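#' Raw EHR-like record collection
#'
#' Bundles the five tables of a primary-care style extract into a validated
#' container: `patients` (one row per patient), `episodes` (coded diagnoses
#' with start dates), `measurements` (dated entries of the four body
#' measurements and smoking status), `prescriptions` (dated, ATC-coded) and
#' `registration` (one row per patient per calendar quarter of the observation
#' window, with a logical `present` flag).
#'
#' Column schemas (all keyed by `patient_id`):
#' * `patients`: `patient_id`, `practice_id`, `birth_date` (Date), `sex`
#'   (`"male"`/`"female"`).
#' * `episodes`: `patient_id`, `code`, `start_date` (Date), optional
#'   `end_date`.
#' * `measurements`: `patient_id`, `kind` (one of `height_cm`, `weight_kg`,
#'   `sbp_mmHg`, `dbp_mmHg`, `smoking_status`), `value` (numeric as character
#'   for the measurements; `current`/`former`/`never` for smoking), `date`.
#' * `prescriptions`: `patient_id`, `atc_code`, `date`.
#' * `registration`: `patient_id`, `quarter_start` (Date, first day of the
#'   quarter), `present` (logical).
#'
#' @param patients,episodes,measurements,prescriptions,registration Data
#'   frames with the columns above.
#' @param window_start,window_end Dates bounding the observation window.
#' @return An object of class `ehr_records`.
#' @export
ehr_records <- function(patients, episodes, measurements, prescriptions,
                        registration,
                        window_start = as.Date("2013-01-01"),
                        window_end = as.Date("2018-12-31")) {
  stop_missing_cols(patients, c("patient_id", "practice_id", "birth_date", "sex"),
                    "`patients`")
  stop_missing_cols(episodes, c("patient_id", "code", "start_date"), "`episodes`")
  stop_missing_cols(measurements, c("patient_id", "kind", "value", "date"),
                    "`measurements`")
  stop_missing_cols(prescriptions, c("patient_id", "atc_code", "date"),
                    "`prescriptions`")
  stop_missing_cols(registration, c("patient_id", "quarter_start", "present"),
                    "`registration`")
  kinds <- c("height_cm", "weight_kg", "sbp_mmHg", "dbp_mmHg", "smoking_status")
  bad_kind <- setdiff(unique(measurements$kind), kinds)
  if (length(bad_kind) > 0L) {
    stop("unknown measurement kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  }
  for (tb in list(episodes$start_date, measurements$date, prescriptions$date)) {
    if (length(tb) > 0L &&
        (min(tb) < window_start || max(tb) > window_end)) {
      stop("dated entries must lie within the observation window", call. = FALSE)
    }
  }
  num <- suppressWarnings(as.numeric(
    measurements$value[measurements$kind != "smoking_status"]))
  if (any(is.na(num)) || any(num <= 0)) {
    stop("numeric measurement values must be positive numbers", call. = FALSE)
  }
  structure(
    list(patients = tibble::as_tibble(patients),
         episodes = tibble::as_tibble(episodes),
         measurements = tibble::as_tibble(measurements),
         prescriptions = tibble::as_tibble(prescriptions),
         registration = tibble::as_tibble(registration)),
    window_start = window_start, window_end = window_end,
    class = "ehr_records")
}

#' @export
print.ehr_records <- function(x, ...) {
  cat(sprintf(
    "ehr_records: %d patients, %d episodes, %d measurements, %d prescriptions (%s to %s)\n",
    nrow(x$patients), nrow(x$episodes), nrow(x$measurements),
    nrow(x$prescriptions),
    attr(x, "window_start"), attr(x, "window_end")))
  invisible(x)
}

#' Read raw records from delimited files
#'
#' Reads the five CSV files written by [write_ehr_records()] (or prepared
#' externally with the same column schema) from a directory and validates them
#' into an [ehr_records()] container. Dates must be ISO `YYYY-MM-DD`.
#'
#' @param dir Directory containing `patients.csv`, `episodes.csv`,
#'   `measurements.csv`, `prescriptions.csv`, `registration.csv`.
#' @inheritParams ehr_records
#' @return An `ehr_records` object.
#' @export
read_ehr_records <- function(dir,
                             window_start = as.Date("2013-01-01"),
                             window_end = as.Date("2018-12-31")) {
  rd <- function(f, datecols) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if ("value" %in% names(df)) df$value <- as.character(df$value)
    for (dc in intersect(datecols, names(df))) df[[dc]] <- as.Date(df[[dc]])
    df
  }
  reg <- rd("registration.csv", "quarter_start")
  reg$present <- as.logical(reg$present)
  ehr_records(
    patients = rd("patients.csv", "birth_date"),
    episodes = rd("episodes.csv", c("start_date", "end_date")),
    measurements = rd("measurements.csv", "date"),
    prescriptions = rd("prescriptions.csv", "date"),
    registration = reg,
    window_start = window_start, window_end = window_end)
}

#' Write raw records to delimited files
#'
#' @param records An [ehr_records()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ehr_records <- function(records, dir) {
  stopifnot(inherits(records, "ehr_records"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(records)) {
    utils::write.csv(records[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

# Completed years between two dates (birthday-exact, not 365.25-based).
age_completed_years <- function(birth_date, at_date) {
  bb <- as.POSIXlt(birth_date); aa <- as.POSIXlt(at_date)
  age <- aa$year - bb$year
  before_birthday <- (aa$mon < bb$mon) | (aa$mon == bb$mon & aa$mday < bb$mday)
  age - as.integer(before_birthday)
}
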