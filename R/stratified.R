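#' Kaplan-Meier failure curves stratified by risk category
#'
#' One product-limit failure curve per non-empty predicted-risk category.
#' For a well-calibrated model each stratum's observed failure at the horizon
#' falls inside that stratum's own predicted-risk band.
#'
#' @param risks Predicted probabilities.
#' @param thresholds Category thresholds (see [categorize_risk()]).
#' @param times,events Follow-up outcome.
#' @param horizon Horizon for the per-stratum failure summary.
#' @return A `stratified_km`: tibble stacking the per-category curves with a
#'   `category` column; the per-stratum failure at the horizon is in
#'   `attr(, "summary")`.
#' @export
stratified_km <- function(risks, thresholds = c(0.025, 0.05), times, events,
                          horizon = 5) {
  cats <- categorize_risk(risks, thresholds)
  lv <- levels(cats)[levels(cats) %in% as.character(unique(cats))]
  curves <- purrr::map_dfr(lv, function(g) {
    idx <- cats == g
    km <- kaplan_meier(times[idx], events[idx])
    dplyr::mutate(tibble::as_tibble(km), category = factor(g, levels = lv),
                  .before = 1L)
  })
  summary <- purrr::map_dfr(lv, function(g) {
    idx <- cats == g
    km <- kaplan_meier(times[idx], events[idx])
    f <- km_failure_at(km, horizon)
    tibble::tibble(category = g, n = sum(idx), n_events = sum(events[idx]),
                   failure_at_horizon = f$failure,
                   se = sqrt(f$var))
  })
  structure(curves, class = c("stratified_km", class(tibble::tibble())),
            summary = summary, horizon = horizon)
}

#' Validation report for one or more predictors, overall and by stratum
#'
#' For each stratum (overall cohort, age >= 65 / < 65, men / women,
#' CHA2DS2-VASc >= 2 / < 2) and each predictor (CHARGE-AF predicted risk, the
#' CHA2DS2-VASc score, age alone), computes the C-statistic with bootstrap CI;
#' for CHARGE-AF additionally the calibration slope of the linear predictor
#' (Wald CI) and the Nam-D'Agostino chi-squared over risk deciles.
#'
#' @param cohort Scored cohort with columns `charge_af_risk5y`,
#'   `charge_af_lp`, `cha2ds2vasc`, `age`, `sex`, `time_years`, `event`.
#' @param min_stratum_n Strata smaller than this are skipped with a warning
#'   (default 50).
#' @param n_groups Calibration groups for the goodness-of-fit test.
#' @param horizon Horizon in years.
#' @param ci Compute bootstrap CIs for the C-statistic?
#' @param B Bootstrap resamples.
#' @param seed Seed for all bootstrap resampling.
#' @return Tibble with one row per stratum x predictor.
#' @export
stratified_validation <- function(cohort, min_stratum_n = 50, n_groups = 10,
                                  horizon = 5, ci = TRUE, B = 200L,
                                  seed = 20140101) {
  stop_missing_cols(cohort, c("charge_af_risk5y", "charge_af_lp", "cha2ds2vasc",
                              "age", "sex", "time_years", "event"), "cohort")
  strata <- list(
    all = rep(TRUE, nrow(cohort)),
    age_ge65 = cohort$age >= 65,
    age_lt65 = cohort$age < 65,
    men = cohort$sex == "male",
    women = cohort$sex == "female",
    cha2ds2vasc_ge2 = cohort$cha2ds2vasc >= 2,
    cha2ds2vasc_lt2 = cohort$cha2ds2vasc < 2)
  predictors <- list(
    charge_af = cohort$charge_af_risk5y,
    cha2ds2vasc = as.numeric(cohort$cha2ds2vasc),
    age = cohort$age)

  purrr::map_dfr(names(strata), function(s) {
    idx <- strata[[s]]
    if (sum(idx) < min_stratum_n) {
      warning(sprintf("stratum '%s' below minimum size (%d < %d); skipped",
                      s, sum(idx), min_stratum_n), call. = FALSE)
      return(NULL)
    }
    tm <- cohort$time_years[idx]; ev <- as_event_int(cohort$event)[idx]
    purrr::map_dfr(names(predictors), function(p) {
      cc <- harrell_c(predictors[[p]][idx], tm, ev, ci = ci, B = B, seed = seed)
      row <- tibble::tibble(
        stratum = s, n = sum(idx), n_events = sum(ev), predictor = p,
        c = cc$c, c_lo = cc$ci_lo, c_hi = cc$ci_hi,
        nd_chisq = NA_real_, nd_df = NA_real_, nd_p = NA_real_,
        slope = NA_real_, slope_lo = NA_real_, slope_hi = NA_real_)
      if (p == "charge_af") {
        ct <- calibration_table(cohort$charge_af_risk5y[idx], tm, ev,
                                n_groups = n_groups, horizon = horizon)
        nd <- nam_dagostino(ct)
        sl <- cox_fit_single(cohort$charge_af_lp[idx], tm, ev)
        row$nd_chisq <- nd$chisq; row$nd_df <- nd$df; row$nd_p <- nd$p_value
        row$slope <- sl$coefficient; row$slope_lo <- sl$ci_lo
        row$slope_hi <- sl$ci_hi
      }
      row
    })
  })
}

#' Full validation report for a scored cohort
#'
#' One-stop assembly of the validation outputs: the stratified
#' discrimination/calibration table, the decile calibration table with the
#' goodness-of-fit test, the risk-category stratified KM curves, NRI of
#' CHARGE-AF versus age alone and versus CHA2DS2-VASc (comparators mapped to
#' absolute risks with [marker_to_risk()]), and the screening triage table.
#'
#' @inheritParams stratified_validation
#' @param thresholds Risk-category thresholds for NRI and stratified KM.
#' @param cutoffs Triage cut-offs.
#' @param stratified Compute the per-stratum table (set `FALSE` for speed)?
#' @return A `charge_af_validation` object (list).
#' @export
validate_charge_af <- function(cohort, thresholds = c(0.025, 0.05),
                               cutoffs = c(0.025, 0.05, 0.10), horizon = 5,
                               n_groups = 10, min_stratum_n = 50, ci = TRUE,
                               B = 200L, seed = 20140101, stratified = TRUE) {
  stop_missing_cols(cohort, c("charge_af_risk5y", "charge_af_lp", "cha2ds2vasc",
                              "age", "sex", "time_years", "event"), "cohort")
  tm <- cohort$time_years; ev <- as_event_int(cohort$event)
  risk <- cohort$charge_af_risk5y
  calib <- calibration_table(risk, tm, ev, n_groups = n_groups, horizon = horizon)
  res <- list(
    n = nrow(cohort), n_events = sum(ev),
    incidence = incidence_rate(tm, ev, horizon = horizon),
    concordance = harrell_c(risk, tm, ev, ci = ci, B = B, seed = seed),
    calibration = calib,
    nam_dagostino = nam_dagostino(calib),
    slope = cox_fit_single(cohort$charge_af_lp, tm, ev),
    km_strata = stratified_km(risk, thresholds, tm, ev, horizon = horizon),
    nri_vs_age = categorical_nri(
      risk, marker_to_risk(cohort$age, tm, ev, horizon = horizon),
      thresholds, tm, ev, horizon = horizon, B = B, seed = seed),
    nri_vs_cha2ds2vasc = categorical_nri(
      risk, marker_to_risk(as.numeric(cohort$cha2ds2vasc), tm, ev,
                           horizon = horizon),
      thresholds, tm, ev, horizon = horizon, B = B, seed = seed),
    triage = triage_table(cohort, cutoffs = cutoffs, horizon = horizon),
    strata_table = if (stratified) {
      stratified_validation(cohort, min_stratum_n = min_stratum_n,
                            n_groups = n_groups, horizon = horizon,
                            ci = ci, B = B, seed = seed)
    })
  structure(res, class = "charge_af_validation")
}

#' @export
print.charge_af_validation <- function(x, ...) {
  cat(sprintf("CHARGE-AF validation: n = %d, events = %d (%.1f%% cumulative, %.1f/1000 PY)\n",
              x$n, x$n_events, 100 * x$incidence$cum_incidence,
              x$incidence$rate_per_1000py))
  cat(sprintf("  C-statistic: %.3f [%.3f, %.3f]\n",
              x$concordance$c, x$concordance$ci_lo, x$concordance$ci_hi))
  cat(sprintf("  Calibration slope: %.2f [%.2f, %.2f]\n",
              x$slope$coefficient, x$slope$ci_lo, x$slope$ci_hi))
  cat(sprintf("  Goodness of fit: chi2 = %.1f (df %d, p = %.3g)\n",
              x$nam_dagostino$chisq, x$nam_dagostino$df, x$nam_dagostino$p_value))
  cat("  NRI vs age:", sprintf("%.3f", x$nri_vs_age$estimates$estimate[1]),
      "| NRI vs CHA2DS2-VASc:",
      sprintf("%.3f", x$nri_vs_cha2ds2vasc$estimates$estimate[1]), "\n")
  invisible(x)
}

#' @rdname validate_charge_af
#' @param x A `charge_af_validation`.
#' @param ... Unused.
#' @method glance charge_af_validation
#' @export
glance.charge_af_validation <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events,
    cum_incidence = x$incidence$cum_incidence,
    rate_per_1000py = x$incidence$rate_per_1000py,
    c_statistic = x$concordance$c,
    c_lo = x$concordance$ci_lo, c_hi = x$concordance$ci_hi,
    calibration_slope = x$slope$coefficient,
    nd_chisq = x$nam_dagostino$chisq, nd_p = x$nam_dagostino$p_value,
    nri_vs_age = x$nri_vs_age$estimates$estimate[1],
    nri_vs_cha2ds2vasc = x$nri_vs_cha2ds2vasc$estimates$estimate[1])
}
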