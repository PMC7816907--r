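#' Extract baseline covariates from raw records
#'
#' Builds one row of baseline covariates per patient in `records`:
#'
#' * Measurements (height, weight, SBP, DBP): among entries dated within
#'   `[baseline_date - window_days, baseline_date)`, the entry closest to
#'   baseline is taken. Two entries of the same kind equally close can only
#'   share a date; the tie is broken deterministically by the lexicographically
#'   smaller value. Kinds with no in-window entry stay `NA` (no imputation).
#' * Smoking: current smoking is `TRUE` iff the most recent
#'   `smoking_status` entry dated before baseline equals `"current"`; patients
#'   with no recorded status count as non-smokers (absence of a record is
#'   taken as absence of the exposure).
#' * Morbidity flags (AF, heart failure, MI, hypertension, diabetes, stroke,
#'   TIA, atherosclerosis, angina): `TRUE` iff any episode with a mapped code
#'   starts before `baseline_date`, optionally limited to a per-condition
#'   lookback window.
#' * Antihypertensive use: `TRUE` iff any prescription with a mapped ATC
#'   prefix is dated within the baseline window.
#'
#' Age is completed years at `baseline_date`. All intervals are closed at the
#' start and open at the end.
#'
#' @param records An [ehr_records()] object.
#' @param baseline_date Baseline date (default 2014-01-01).
#' @param window_days Length of the baseline measurement window in days
#'   (default 365: the calendar year before a Jan 1 baseline).
#' @param map A [code_map()].
#' @param lookback_days Optional named numeric vector of per-condition
#'   lookback windows in days; conditions not named use an unlimited lookback.
#' @return Tibble with one row per patient: identifiers, `age`, `sex`, the
#'   four measurements, `smoking`, `antihypertensive`, the morbidity flags,
#'   `prevalent_af`, and `ethnicity_white` (constant `TRUE`; the model's
#'   ethnicity term is retained because dropping it would systematically
#'   underestimate absolute risk).
#' @export
extract_baseline <- function(records, baseline_date = as.Date("2014-01-01"),
                             window_days = 365, map = code_map(),
                             lookback_days = NULL) {
  stopifnot(inherits(records, "ehr_records"))
  baseline_date <- as.Date(baseline_date)
  if (window_days <= 0) stop("`window_days` must be positive", call. = FALSE)
  if (baseline_date <= attr(records, "window_start") ||
      baseline_date > attr(records, "window_end")) {
    stop("`baseline_date` must lie inside the observation window", call. = FALSE)
  }
  window_start <- baseline_date - window_days

  pts <- records$patients
  out <- tibble::tibble(
    patient_id = pts$patient_id,
    practice_id = pts$practice_id,
    sex = pts$sex,
    age = age_completed_years(pts$birth_date, baseline_date),
    ethnicity_white = TRUE
  )

  # nearest-to-baseline measurement per kind; order of the input rows is
  # irrelevant because the selection sorts on (date desc, value asc)
  meas <- dplyr::filter(records$measurements,
                        .data$date >= window_start, .data$date < baseline_date)
  num_kinds <- c(height = "height_cm", weight = "weight_kg",
                 sbp = "sbp_mmHg", dbp = "dbp_mmHg")
  picked <- meas |>
    dplyr::filter(.data$kind %in% num_kinds) |>
    dplyr::arrange(.data$patient_id, .data$kind,
                   dplyr::desc(.data$date), .data$value) |>
    dplyr::distinct(.data$patient_id, .data$kind, .keep_all = TRUE) |>
    dplyr::mutate(value_num = as.numeric(.data$value)) |>
    dplyr::select("patient_id", "kind", "value_num") |>
    tidyr::pivot_wider(names_from = "kind", values_from = "value_num")
  for (nm in names(num_kinds)) {
    col <- num_kinds[[nm]]
    vals <- if (col %in% names(picked)) picked[[col]] else rep(NA_real_, nrow(picked))
    out[[nm]] <- vals[match(out$patient_id, picked$patient_id)]
  }

  smoke <- records$measurements |>
    dplyr::filter(.data$kind == "smoking_status", .data$date < baseline_date) |>
    dplyr::arrange(.data$patient_id, dplyr::desc(.data$date), .data$value) |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE)
  out$smoking <- !is.na(match(out$patient_id, smoke$patient_id)) &
    smoke$value[match(out$patient_id, smoke$patient_id)] %in% "current"

  conds <- map$conditions
  flag_names <- c(prevalent_af = "atrial_fibrillation",
                  heart_failure = "heart_failure",
                  myocardial_infarction = "myocardial_infarction",
                  hypertension = "hypertension", diabetes = "diabetes",
                  stroke = "stroke", tia = "tia",
                  atherosclerosis = "atherosclerosis", angina = "angina")
  for (nm in names(flag_names)) {
    cond <- flag_names[[nm]]
    lb <- if (!is.null(lookback_days) && cond %in% names(lookback_days)) {
      baseline_date - lookback_days[[cond]]
    } else {
      as.Date("0001-01-01")
    }
    hits <- records$episodes$patient_id[
      records$episodes$code %in% conds[[cond]] &
        records$episodes$start_date < baseline_date &
        records$episodes$start_date >= lb]
    out[[nm]] <- out$patient_id %in% hits
  }

  aht_prefixes <- map$medications$antihypertensive
  rx <- dplyr::filter(records$prescriptions,
                      .data$date >= window_start, .data$date < baseline_date)
  aht_hit <- rx$patient_id[
    Reduce(`|`, lapply(aht_prefixes, function(p) startsWith(rx$atc_code, p)),
           accumulate = FALSE) %||% logical(0)]
  out$antihypertensive <- out$patient_id %in% aht_hit
  out
}

#' Apply the eligibility filter and record the cohort flow
#'
#' Retains patients who are (in order of accounting) aged >= 40 at baseline,
#' free of AF before baseline, registered during all four quarters of the
#' baseline year, and whose practice has any registration data after baseline.
#' The final set does not depend on the filter order; the flow table only
#' decomposes the attrition.
#'
#' @param records An [ehr_records()] object.
#' @param baseline_date Baseline date.
#' @param map A [code_map()] (for the AF codes).
#' @return List with `records` (the filtered `ehr_records`) and `flow`, a
#'   tibble of `step` / `n` with monotonically non-increasing counts.
#' @export
apply_eligibility <- function(records, baseline_date = as.Date("2014-01-01"),
                              map = code_map()) {
  stopifnot(inherits(records, "ehr_records"))
  baseline_date <- as.Date(baseline_date)
  pts <- records$patients
  if (nrow(pts) == 0L) {
    flow <- tibble::tibble(
      step = c("total", "age_ge40", "af_free", "registered_baseline_year",
               "practice_has_followup"),
      n = rep(0L, 5))
    return(list(records = records, flow = flow))
  }

  age <- age_completed_years(pts$birth_date, baseline_date)
  ok_age <- age >= 40

  af_codes <- map$conditions$atrial_fibrillation
  af_before <- unique(records$episodes$patient_id[
    records$episodes$code %in% af_codes &
      records$episodes$start_date < baseline_date])
  ok_af <- !(pts$patient_id %in% af_before)

  baseline_year_start <- baseline_date - 365
  reg <- records$registration
  base_reg <- reg[reg$quarter_start >= baseline_year_start &
                    reg$quarter_start < baseline_date, , drop = FALSE]
  full_year <- dplyr::summarise(
    dplyr::group_by(base_reg, .data$patient_id),
    ok = sum(.data$present) >= 4L, .groups = "drop")
  ok_reg <- pts$patient_id %in% full_year$patient_id[full_year$ok]

  post <- reg[reg$quarter_start >= baseline_date & reg$present, , drop = FALSE]
  practices_with_fu <- unique(
    pts$practice_id[match(post$patient_id, pts$patient_id)])
  ok_practice <- pts$practice_id %in% practices_with_fu

  keep <- ok_age & ok_af & ok_reg & ok_practice
  flow <- tibble::tibble(
    step = c("total", "age_ge40", "af_free", "registered_baseline_year",
             "practice_has_followup"),
    n = c(nrow(pts), sum(ok_age), sum(ok_age & ok_af),
          sum(ok_age & ok_af & ok_reg), sum(keep)))

  ids <- pts$patient_id[keep]
  filt <- function(df) df[df$patient_id %in% ids, , drop = FALSE]
  out <- ehr_records(
    patients = filt(pts), episodes = filt(records$episodes),
    measurements = filt(records$measurements),
    prescriptions = filt(records$prescriptions),
    registration = filt(records$registration),
    window_start = attr(records, "window_start"),
    window_end = attr(records, "window_end"))
  list(records = out, flow = flow)
}

#' Split a cohort into complete and incomplete cases
#'
#' A complete case has all four body measurements (`height`, `weight`, `sbp`,
#' `dbp`) recorded at baseline; the partition is exhaustive and disjoint.
#'
#' @param cohort Cohort tibble with the four measurement columns.
#' @return List with tibbles `complete` and `incomplete`.
#' @export
split_complete_cases <- function(cohort) {
  stop_missing_cols(cohort, c("height", "weight", "sbp", "dbp"), "cohort")
  ok <- stats::complete.cases(cohort[, c("height", "weight", "sbp", "dbp")])
  list(complete = tibble::as_tibble(cohort[ok, , drop = FALSE]),
       incomplete = tibble::as_tibble(cohort[!ok, , drop = FALSE]))
}

#' Compare baseline variables between two groups
#'
#' Continuous variables are compared with Welch's unequal-variance t-test,
#' ordinal integer scores with the Wilcoxon rank-sum test, and binary
#' variables with the chi-squared test (without continuity correction).
#'
#' @param group1,group2 Cohort tibbles.
#' @param variables Character vector of column names to compare.
#' @param types Optional named character vector overriding the per-variable
#'   test (`"continuous"`, `"ordinal"`, `"binary"`).
#' @return Tibble with per-variable group summaries (mean for continuous,
#'   median for ordinal, proportion for binary) and the p-value. Zero-variance
#'   continuous variables are skipped with a warning (`NA` p-value).
#' @export
compare_groups <- function(group1, group2, variables, types = NULL) {
  stopifnot(nrow(group1) > 0, nrow(group2) > 0)
  infer_type <- function(x) {
    if (is.logical(x) || (is.numeric(x) && all(x %in% c(0, 1), na.rm = TRUE))) {
      "binary"
    } else if (is.integer(x)) {
      "ordinal"
    } else {
      "continuous"
    }
  }
  purrr::map_dfr(variables, function(v) {
    x1 <- group1[[v]]; x2 <- group2[[v]]
    tp <- if (!is.null(types) && v %in% names(types)) types[[v]] else infer_type(x1)
    if (tp == "binary") {
      tab <- rbind(c(sum(x1, na.rm = TRUE), sum(!x1, na.rm = TRUE)),
                   c(sum(x2, na.rm = TRUE), sum(!x2, na.rm = TRUE)))
      p <- stats::chisq.test(tab, correct = FALSE)$p.value
      s1 <- mean(x1, na.rm = TRUE); s2 <- mean(x2, na.rm = TRUE)
      test <- "chi-squared"
    } else if (tp == "ordinal") {
      p <- stats::wilcox.test(x1, x2, exact = FALSE)$p.value
      s1 <- stats::median(x1, na.rm = TRUE); s2 <- stats::median(x2, na.rm = TRUE)
      test <- "wilcoxon"
    } else {
      if (stats::var(x1, na.rm = TRUE) == 0 && stats::var(x2, na.rm = TRUE) == 0) {
        warning(sprintf("variable '%s' has zero variance in both groups; test skipped", v),
                call. = FALSE)
        p <- NA_real_
      } else {
        p <- stats::t.test(x1, x2)$p.value
      }
      s1 <- mean(x1, na.rm = TRUE); s2 <- mean(x2, na.rm = TRUE)
      test <- "welch-t"
    }
    tibble::tibble(variable = v, type = tp, test = test,
                   group1 = s1, group2 = s2, p_value = p)
  })
}
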