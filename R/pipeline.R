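# Batch entry points: thin CSV-in / CSV-out wrappers over the package
# functions, used by the command-line script in inst/cli. All file I/O is
# CSV for auditability; every run writes a provenance block.

write_provenance <- function(dir, what, seed, extra = list()) {
  prov <- c(list(tool = "chargeaf",
                 version = as.character(utils::packageVersion("chargeaf")),
                 what = what, seed = seed,
                 timestamp = format(Sys.time(), tz = "UTC")), extra)
  path <- file.path(dir, "provenance.json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    writeLines(paste(names(prov), vapply(prov, function(x)
      paste(format(x), collapse = " "), character(1)), sep = ": "), path)
  }
  invisible(path)
}

#' Simulate a synthetic cohort to disk
#'
#' Writes `cohort.csv` (flat analysis table) and the five raw-record CSVs
#' plus a provenance file (package version, seed, config hash, solved
#' calibration parameters).
#'
#' @param output_dir Output directory (created if needed).
#' @param n Cohort size.
#' @param seed Integer seed.
#' @param config An [af_cohort_config()].
#' @param raw Also emit raw EHR-like records?
#' @return The cohort tibble, invisibly.
#' @export
run_simulate <- function(output_dir, n = 10000, seed = 20140101,
                         config = af_cohort_config(), raw = TRUE) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  cohort <- generate_cohort(n, config, seed = seed)
  utils::write.csv(cohort, file.path(output_dir, "cohort.csv"),
                   row.names = FALSE)
  if (raw) {
    write_ehr_records(emit_raw_records(cohort, config, seed = seed + 4),
                      output_dir)
  }
  write_provenance(
    output_dir, "simulate", seed,
    list(n = n,
         config_hash = attr(cohort, "provenance")$config_hash,
         hazard_multiplier = attr(cohort, "hazard_multiplier"),
         dropout_quarterly = attr(cohort, "dropout_quarterly")))
  invisible(cohort)
}

read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in intersect(names(df),
                       c("smoking", "antihypertensive", "hypertension",
                         "diabetes", "heart_failure", "myocardial_infarction",
                         "stroke", "tia", "atherosclerosis", "angina",
                         "ethnicity_white", "complete", "event"))) {
    df[[nm]] <- as.logical(df[[nm]])
  }
  tibble::as_tibble(df)
}

#' Validate a scored cohort and write the report files
#'
#' Scores the cohort if score columns are absent, runs
#' [validate_charge_af()], and writes: `validation_report.csv` (the stratum x
#' predictor table), `calibration.csv`, `km_strata.csv`, `nri.csv`,
#' `triage.csv` and a provenance file.
#'
#' @param cohort A cohort tibble or path to a cohort CSV with the
#'   covariate and outcome columns.
#' @param output_dir Output directory.
#' @param ... Passed to [validate_charge_af()].
#' @param seed Seed for bootstrap resampling.
#' @param complete_only Restrict to complete cases first (default `TRUE`)?
#' @return The `charge_af_validation` object, invisibly.
#' @export
run_validate <- function(cohort, output_dir, ..., seed = 20140101,
                         complete_only = TRUE) {
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  stop_missing_cols(cohort, c("age", "sex", "time_years", "event"), "cohort")
  if (complete_only) cohort <- split_complete_cases(cohort)$complete
  if (!"charge_af_risk5y" %in% names(cohort)) cohort <- score_cohort(cohort)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  rep <- validate_charge_af(cohort, ..., seed = seed)
  utils::write.csv(rep$strata_table %||% glance(rep),
                   file.path(output_dir, "validation_report.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$calibration, file.path(output_dir, "calibration.csv"),
                   row.names = FALSE)
  utils::write.csv(tibble::as_tibble(rep$km_strata),
                   file.path(output_dir, "km_strata.csv"), row.names = FALSE)
  nri <- dplyr::bind_rows(
    dplyr::mutate(rep$nri_vs_age$estimates, comparator = "age"),
    dplyr::mutate(rep$nri_vs_cha2ds2vasc$estimates,
                  comparator = "cha2ds2vasc"))
  utils::write.csv(nri, file.path(output_dir, "nri.csv"), row.names = FALSE)
  utils::write.csv(rep$triage, file.path(output_dir, "triage.csv"),
                   row.names = FALSE)
  write_provenance(output_dir, "validate", seed,
                   list(n = rep$n, n_events = rep$n_events))
  invisible(rep)
}

#' Compute and write a triage table
#'
#' @inheritParams run_validate
#' @param cutoffs Risk cut-offs.
#' @param horizon Horizon in years.
#' @return The triage tibble, invisibly.
#' @export
run_triage <- function(cohort, output_dir, cutoffs = c(0.025, 0.05, 0.10),
                       horizon = 5, seed = 20140101, complete_only = TRUE) {
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  if (complete_only) cohort <- split_complete_cases(cohort)$complete
  if (!"charge_af_risk5y" %in% names(cohort)) cohort <- score_cohort(cohort)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  tt <- triage_table(cohort, cutoffs = cutoffs, horizon = horizon)
  utils::write.csv(tt, file.path(output_dir, "triage.csv"), row.names = FALSE)
  write_provenance(output_dir, "triage", seed, list(n = nrow(cohort)))
  invisible(tt)
}
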