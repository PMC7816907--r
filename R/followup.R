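#' Loss-to-follow-up date from a quarterly registration grid
#'
#' Registration is assessed per calendar quarter. Loss to follow-up is the
#' first day of the earliest run of absent quarters that either (a) spans at
#' least `min_run` consecutive quarters, or (b) includes the final quarter of
#' the observation window. Death is indistinguishable from other loss in this
#' kind of registry, so no competing-risk distinction is made.
#'
#' @param present Logical vector, one element per calendar quarter.
#' @param quarter_starts Date vector of the same length: first day of each
#'   quarter, in order.
#' @param min_run Minimum run length that triggers loss mid-window (default 4).
#' @return The loss date, or `NA` (Date) if follow-up is complete.
#' @examples
#' qs <- seq(as.Date("2014-01-01"), by = "quarter", length.out = 8)
#' loss_to_followup_date(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE), qs)
#' @export
loss_to_followup_date <- function(present, quarter_starts, min_run = 4L) {
  if (length(present) != length(quarter_starts)) {
    stop("`present` and `quarter_starts` must have equal length", call. = FALSE)
  }
  if (length(present) == 0L) stop("empty registration grid", call. = FALSE)
  r <- rle(present)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  absent <- !r$values
  trigger <- absent & (r$lengths >= min_run | ends == length(present))
  if (!any(trigger)) return(as.Date(NA))
  quarter_starts[starts[which(trigger)[1L]]]
}

#' Resolve a censored time-to-event outcome
#'
#' Follow-up ends at the earliest of AF diagnosis, loss to follow-up, and the
#' end of the observation horizon; the event indicator is `TRUE` only when the
#' AF date comes first (ties with a censoring date count as events). An AF
#' diagnosis dated after loss to follow-up is unobservable and the patient is
#' censored at the loss date. Times are converted at 365.25 days per year.
#'
#' @param af_date,loss_date Date vectors (NA where absent), recycled to a
#'   common length.
#' @param baseline Baseline date.
#' @param horizon_end Administrative end of the observation window.
#' @return Tibble with `time_years`, `event` (logical) and `censor_reason`
#'   (`af_event`, `lost_to_followup` or `admin_end`).
#' @export
resolve_outcome <- function(af_date, loss_date,
                            baseline = as.Date("2014-01-01"),
                            horizon_end = as.Date("2018-12-31")) {
  n <- max(length(af_date), length(loss_date))
  af_date <- rep_len(as.Date(af_date), n)
  loss_date <- rep_len(as.Date(loss_date), n)
  baseline <- as.Date(baseline); horizon_end <- as.Date(horizon_end)
  if (any(!is.na(af_date) & af_date < baseline)) {
    stop("AF date before baseline: prevalent AF should have been excluded upstream",
         call. = FALSE)
  }
  censor_date <- pmin(loss_date, horizon_end, na.rm = TRUE)
  is_event <- !is.na(af_date) & af_date <= censor_date
  end_date <- dplyr::if_else(is_event, af_date, censor_date)
  reason <- dplyr::case_when(
    is_event ~ "af_event",
    !is.na(loss_date) & loss_date <= horizon_end ~ "lost_to_followup",
    TRUE ~ "admin_end")
  tibble::tibble(
    time_years = as.numeric(end_date - baseline) / 365.25,
    event = is_event,
    censor_reason = reason)
}

#' Derive outcomes for every patient in a raw-record collection
#'
#' Combines the first post-baseline AF episode date, the quarterly
#' loss-to-follow-up rule and the administrative horizon into one outcome row
#' per patient.
#'
#' @param records An [ehr_records()] object (post-eligibility).
#' @inheritParams resolve_outcome
#' @param map A [code_map()].
#' @param min_run Passed to [loss_to_followup_date()].
#' @return Tibble: `patient_id`, `time_years`, `event`, `censor_reason`.
#' @export
derive_followup <- function(records, baseline = as.Date("2014-01-01"),
                            horizon_end = as.Date("2018-12-31"),
                            map = code_map(), min_run = 4L) {
  stopifnot(inherits(records, "ehr_records"))
  baseline <- as.Date(baseline)
  af_codes <- map$conditions$atrial_fibrillation
  af <- records$episodes |>
    dplyr::filter(.data$code %in% af_codes, .data$start_date >= baseline) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(af_date = min(.data$start_date), .groups = "drop")

  reg <- records$registration |>
    dplyr::filter(.data$quarter_start >= baseline) |>
    dplyr::arrange(.data$patient_id, .data$quarter_start)
  loss <- reg |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      loss_date = loss_to_followup_date(.data$present, .data$quarter_start,
                                        min_run = min_run),
      .groups = "drop")

  ids <- records$patients$patient_id
  out <- resolve_outcome(
    af_date = af$af_date[match(ids, af$patient_id)],
    loss_date = loss$loss_date[match(ids, loss$patient_id)],
    baseline = baseline, horizon_end = horizon_end)
  dplyr::bind_cols(tibble::tibble(patient_id = ids), out)
}

#' Kaplan-Meier survival curve with Greenwood variance
#'
#' Product-limit estimator of the survival (and failure) function; the
#' variance at each event time is Greenwood's formula
#' \eqn{S(t)^2 \sum d_i / (n_i (n_i - d_i))}. Events precede censorings at
#' tied times (standard risk-set convention). Backed by
#' [survival::survfit()].
#'
#' @param times Positive follow-up times.
#' @param events Logical or 0/1 event indicators.
#' @return A `km_curve`: tibble with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`, `failure`, `var_greenwood`.
#' @examples
#' kaplan_meier(c(1, 2, 3, 4), c(1, 0, 1, 0))
#' @export
kaplan_meier <- function(times, events) {
  events <- as_event_int(events)
  check_times_events(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  d <- fit$n.event; n <- fit$n.risk; s <- fit$surv
  term <- ifelse(n - d > 0, d / (n * (n - d)), Inf)
  v <- s^2 * cumsum(term)
  v[s == 0] <- 0 # degenerate estimate: variance taken as 0
  structure(
    tibble::tibble(
      time = fit$time, n_risk = n, n_event = d, n_censor = fit$n.censor,
      survival = s, failure = 1 - s,
      var_greenwood = v),
    class = c("km_curve", "tbl_df", "tbl", "data.frame"),
    n = length(times))
}

#' Failure probability (and its variance) at a time point
#'
#' Reads the Kaplan-Meier failure estimate at `at`; the step function is
#' right-continuous. Returns the estimate at the last observed time when `at`
#' exceeds follow-up.
#'
#' @param km A [kaplan_meier()] curve.
#' @param at Time point.
#' @return Named list with `failure` and `var`.
#' @export
km_failure_at <- function(km, at) {
  stopifnot(inherits(km, "km_curve"))
  idx <- findInterval(at, km$time)
  if (idx == 0L) return(list(failure = 0, var = 0))
  list(failure = km$failure[idx], var = km$var_greenwood[idx])
}

#' Incidence rate and cumulative incidence
#'
#' Crude incidence rate per 1000 person-years plus the Kaplan-Meier
#' cumulative incidence at the horizon.
#'
#' @param times Positive follow-up times (years).
#' @param events Event indicators.
#' @param horizon Horizon in years (default 5).
#' @return Tibble with `n`, `events`, `person_years`, `rate_per_1000py`,
#'   `cum_incidence`.
#' @export
incidence_rate <- function(times, events, horizon = 5) {
  events <- as_event_int(events)
  check_times_events(times, events)
  if (sum(times) <= 0) stop("zero total person-time", call. = FALSE)
  km <- kaplan_meier(times, events)
  tibble::tibble(
    n = length(times),
    events = sum(events),
    person_years = sum(times),
    rate_per_1000py = 1000 * sum(events) / sum(times),
    cum_incidence = km_failure_at(km, horizon)$failure)
}
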