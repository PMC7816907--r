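#' Screening triage table over risk cut-offs
#'
#' Evaluates dichotomising baseline predicted risk at each cut-off into
#' high (risk >= cut-off, closed boundary: a patient exactly at the cut-off
#' is screened) versus low. Per cut-off the table reports the share of
#' patients counted high risk, the share of all observed AF cases captured
#' (sensitivity, crude 5-year case counts in keeping with a screening-yield
#' reading), the KM cumulative incidence and crude rate among high-risk
#' patients, the share of high-risk patients (and of high-risk AF cases) with
#' CHA2DS2-VASc >= 2 (the anticoagulation-relevant group), the unadjusted
#' high-vs-low hazard ratio from a Cox model, and a chi-squared p-value for
#' the difference in CHA2DS2-VASc >= 2 between high- and low-risk AF cases.
#'
#' @param cohort Scored cohort with `charge_af_risk5y`, `cha2ds2vasc`,
#'   `time_years`, `event`.
#' @param cutoffs Cut-offs in `[0, 1)` (default 2.5%, 5%, 10%).
#' @param horizon Horizon in years.
#' @param risk_col Column holding the predicted risk.
#' @return Tibble with one row per cut-off.
#' @export
triage_table <- function(cohort, cutoffs = c(0.025, 0.05, 0.10), horizon = 5,
                         risk_col = "charge_af_risk5y") {
  if (length(cutoffs) == 0L) stop("`cutoffs` must be non-empty", call. = FALSE)
  if (any(cutoffs < 0 | cutoffs >= 1)) {
    stop("`cutoffs` must lie in [0, 1)", call. = FALSE)
  }
  stop_missing_cols(cohort, c(risk_col, "cha2ds2vasc", "time_years", "event"),
                    "cohort")
  risk <- cohort[[risk_col]]
  tm <- cohort$time_years; ev <- as_event_int(cohort$event)
  vasc2 <- cohort$cha2ds2vasc >= 2
  af_total <- sum(ev)
  purrr::map_dfr(cutoffs, function(cf) {
    high <- risk >= cf
    n_high <- sum(high)
    af_high <- sum(ev[high])
    hr <- hr_lo <- hr_hi <- NA_real_
    if (n_high == 0L || n_high == length(risk)) {
      warning(sprintf("cut-off %.3f: empty high or low group; HR undefined", cf),
              call. = FALSE)
    } else {
      fit <- cox_fit_single(as.numeric(high), tm, ev)
      hr <- fit$hr; hr_lo <- exp(fit$ci_lo); hr_hi <- exp(fit$ci_hi)
    }
    inc_high <- if (n_high > 0L) {
      km_failure_at(kaplan_meier(tm[high], ev[high]), horizon)$failure
    } else NA_real_
    p_vasc <- NA_real_
    af_low_vasc <- sum(vasc2[!high & ev == 1L])
    af_low <- af_total - af_high
    if (af_high > 0L && af_low > 0L) {
      tab <- rbind(c(sum(vasc2[high & ev == 1L]), af_high - sum(vasc2[high & ev == 1L])),
                   c(af_low_vasc, af_low - af_low_vasc))
      if (all(colSums(tab) > 0)) {
        p_vasc <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      }
    }
    tibble::tibble(
      cutoff = cf,
      n_high = n_high,
      pct_high = 100 * n_high / length(risk),
      af_cases_high = af_high,
      sensitivity = if (af_total > 0L) af_high / af_total else NA_real_,
      cum_incidence_high = inc_high,
      rate_high_per_1000py = if (n_high > 0L) 1000 * af_high / sum(tm[high]) else NA_real_,
      pct_high_vasc_ge2 = if (n_high > 0L) 100 * mean(vasc2[high]) else NA_real_,
      pct_high_af_vasc_ge2 = if (af_high > 0L) {
        100 * sum(vasc2[high & ev == 1L]) / af_high
      } else NA_real_,
      hr_high_vs_low = hr, hr_lo = hr_lo, hr_hi = hr_hi,
      p_vasc_diff = p_vasc)
  })
}

#' Sensitivity of a risk cut-off as a triage test
#'
#' For each cut-off on a grid: the share of patients selected (high risk) and
#' the share of all observed AF cases among them. Both are non-increasing
#' step functions of the cut-off; sensitivity is 1 at cut-off 0.
#'
#' @param cohort Scored cohort (see [triage_table()]).
#' @param cutoff_grid Numeric grid in `[0, 1)`.
#' @inheritParams triage_table
#' @return Tibble with `cutoff`, `n_high`, `pct_high`, `sensitivity`.
#' @export
sensitivity_curve <- function(cohort, cutoff_grid = seq(0, 0.2, by = 0.005),
                              risk_col = "charge_af_risk5y") {
  if (any(cutoff_grid < 0 | cutoff_grid >= 1)) {
    stop("`cutoff_grid` must lie in [0, 1)", call. = FALSE)
  }
  risk <- cohort[[risk_col]]
  ev <- as_event_int(cohort$event)
  af_total <- sum(ev)
  purrr::map_dfr(sort(cutoff_grid), function(cf) {
    high <- risk >= cf
    tibble::tibble(
      cutoff = cf, n_high = sum(high),
      pct_high = 100 * mean(high),
      sensitivity = if (af_total > 0L) sum(ev[high]) / af_total else NA_real_)
  })
}
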