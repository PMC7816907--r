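#' Calibration table over risk groups
#'
#' Ranks patients by predicted risk (ties broken by `ids` so grouping is
#' reproducible), splits them into `n_groups` near-equal groups (deciles by
#' default), and compares each group's mean predicted risk with the observed
#' Kaplan-Meier failure probability at the horizon, with a Greenwood-based
#' 95% CI.
#'
#' @param risks Predicted probabilities in (0, 1).
#' @param times Positive follow-up times.
#' @param events Event indicators.
#' @param n_groups Number of risk groups (default 10).
#' @param horizon Horizon for the observed risk (default 5).
#' @param ids Optional stable tie-break key (default input order).
#' @param conf_level CI level.
#' @param min_events Minimum observed events per group: adjacent groups are
#'   merged (upward in risk order) until every group reaches this count.
#'   Sparse-event groups sit outside the asymptotic regime of the
#'   goodness-of-fit statistic, and requiring about 5 or more events per
#'   group is standard practice for survival calibration tests; 0 (default)
#'   disables merging.
#' @return A `calibration_table`: tibble with `group`, `n`, `n_events`,
#'   `risk_mean`, `km_failure`, `km_var`, `ci_lo`, `ci_hi`. Groups with no
#'   patient at risk at the horizon start carry an undefined (`NA`) CI.
#' @export
calibration_table <- function(risks, times, events, n_groups = 10,
                              horizon = 5, ids = NULL, conf_level = 0.95,
                              min_events = 0) {
  events <- as_event_int(events)
  check_times_events(times, events)
  if (any(risks <= 0 | risks >= 1)) {
    stop("`risks` must be strictly inside (0, 1)", call. = FALSE)
  }
  n <- length(risks)
  ids <- ids %||% seq_len(n)
  ord <- order(risks, ids)
  grp <- ceiling(seq_len(n) * n_groups / n)[order(ord)]  # group per input row
  if (min_events > 0) {
    # merge each sparse group into the next one up (the top group, if
    # sparse, merges downward)
    repeat {
      lv <- sort(unique(grp))
      ev_per <- vapply(lv, function(g) sum(events[grp == g]), numeric(1))
      if (all(ev_per >= min_events) || length(lv) <= 1L) break
      g_bad <- lv[which(ev_per < min_events)[1]]
      pos <- match(g_bad, lv)
      target <- if (pos < length(lv)) lv[pos + 1L] else lv[pos - 1L]
      grp[grp == g_bad] <- target
    }
    grp <- match(grp, sort(unique(grp)))  # relabel 1..G'
  }
  n_groups <- max(grp)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- purrr::map_dfr(seq_len(n_groups), function(g) {
    idx <- which(grp == g)
    if (length(idx) == 0L) return(NULL)
    km <- kaplan_meier(times[idx], events[idx])
    at_risk_horizon <- any(times[idx] >= horizon)
    f <- km_failure_at(km, horizon)
    se <- sqrt(f$var)
    tibble::tibble(
      group = g, n = length(idx), n_events = sum(events[idx]),
      risk_mean = mean(risks[idx]),
      km_failure = f$failure, km_var = f$var,
      ci_lo = if (at_risk_horizon) max(0, f$failure - z * se) else NA_real_,
      ci_hi = if (at_risk_horizon) min(1, f$failure + z * se) else NA_real_)
  })
  structure(out, class = c("calibration_table", class(tibble::tibble())),
            horizon = horizon)
}

#' Nam-D'Agostino style goodness-of-fit test for survival calibration
#'
#' Hosmer-Lemeshow-type chi-squared statistic comparing Kaplan-Meier observed
#' failure with mean predicted risk across risk groups; p < 0.05 indicates
#' insufficient calibration. Two standardisations are available:
#'
#' * `"greenwood"` (default): \eqn{\sum_g (KM_g - \bar p_g)^2 / \widehat{Var}(KM_g)}
#'   with the Greenwood variance of each group's KM estimate. Under censoring
#'   the binomial denominator understates the sampling variance of the
#'   observed risk and inflates the statistic; the Greenwood form keeps the
#'   nominal type-I error level.
#' * `"binomial"`: the classical \eqn{\sum_g n_g (KM_g - \bar p_g)^2 /
#'   (\bar p_g (1 - \bar p_g))}.
#'
#' In external validation no parameter is estimated from the grouped data, so
#' all `G` standardised deviations contribute and the default reference
#' distribution is chi-squared with `G` degrees of freedom; `df = "G-1"` gives
#' the internal-validation convention.
#'
#' @param table A [calibration_table()].
#' @param variance `"greenwood"` or `"binomial"`.
#' @param df `"G"` (default) or `"G-1"`.
#' @return Tibble with `chisq`, `df`, `p_value`, `n_groups_used`, `variance`.
#' @export
nam_dagostino <- function(table, variance = c("greenwood", "binomial"),
                          df = c("G", "G-1")) {
  stopifnot(inherits(table, "calibration_table"))
  variance <- match.arg(variance)
  df <- match.arg(df)
  if (nrow(table) < 2L) stop("need at least 2 groups with defined KM", call. = FALSE)
  tab <- table
  if (variance == "binomial") {
    bad <- tab$risk_mean <= 0 | tab$risk_mean >= 1
  } else {
    bad <- !is.finite(tab$km_var) | tab$km_var <= 0
  }
  if (any(bad)) {
    warning(sprintf("%d group(s) with degenerate variance excluded", sum(bad)),
            call. = FALSE)
    tab <- tab[!bad, , drop = FALSE]
  }
  G <- nrow(tab)
  if (G < 2L) stop("fewer than 2 usable groups", call. = FALSE)
  chisq <- if (variance == "binomial") {
    sum(tab$n * (tab$km_failure - tab$risk_mean)^2 /
          (tab$risk_mean * (1 - tab$risk_mean)))
  } else {
    sum((tab$km_failure - tab$risk_mean)^2 / tab$km_var)
  }
  dof <- if (df == "G") G else G - 1L
  tibble::tibble(chisq = chisq, df = dof,
                 p_value = stats::pchisq(chisq, dof, lower.tail = FALSE),
                 n_groups_used = G, variance = variance)
}

#' Categorical net reclassification improvement under censoring
#'
#' Cross-classifies patients into risk categories under a new and a reference
#' model and measures the net proportion of events reclassified upward plus
#' non-events reclassified downward. Event status at the horizon is estimated
#' censoring-aware by Kaplan-Meier within the upward- and downward-moved
#' groups:
#' \deqn{NRI_{ev} = [n_{up} F_{up} - n_{down} F_{down}] / (n F),\quad
#'       NRI_{ne} = [n_{down}(1-F_{down}) - n_{up}(1-F_{up})] / (n(1-F))}
#' with \eqn{F} the overall KM failure at the horizon. Without censoring this
#' reduces to the closed-form contingency-table NRI, and the decomposition
#' `overall = events + nonevents` holds exactly by construction. The CI is a
#' seeded percentile bootstrap over patients.
#'
#' Both risk vectors must be on the probability scale; convert marker
#' comparators with [marker_to_risk()] first.
#'
#' @param risk_new,risk_ref Predicted probabilities under the two models.
#' @param thresholds Category thresholds (default `c(0.025, 0.05)`).
#' @param times,events Follow-up outcome.
#' @param horizon Horizon.
#' @param B Bootstrap resamples (default 200).
#' @param seed Bootstrap seed.
#' @param conf_level CI level.
#' @return An `nri_result`: list with `estimates` (tibble of component /
#'   estimate / CI), the reclassification `table`, `B`, `thresholds`.
#' @export
categorical_nri <- function(risk_new, risk_ref, thresholds = c(0.025, 0.05),
                            times, events, horizon = 5, B = 200L,
                            seed = 20140101, conf_level = 0.95) {
  events <- as_event_int(events)
  check_times_events(times, events)
  stopifnot(length(risk_new) == length(times), length(risk_ref) == length(times))
  cat_new <- as.integer(categorize_risk(risk_new, thresholds))
  cat_ref <- as.integer(categorize_risk(risk_ref, thresholds))
  if (length(unique(paste(cat_new, cat_ref))) == 1L) {
    warning("degenerate category occupancy: all patients in one cell; NRI is 0",
            call. = FALSE)
  }
  point <- nri_point(cat_new, cat_ref, times, events, horizon)
  boot <- withr_seed(seed, {
    n <- length(times)
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      nri_point(cat_new[idx], cat_ref[idx], times[idx], events[idx], horizon)
    }, numeric(3))
  })
  alpha <- (1 - conf_level) / 2
  ci <- apply(boot, 1L, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  structure(
    list(
      estimates = tibble::tibble(
        component = c("overall", "events", "nonevents"),
        estimate = unname(point),
        ci_lo = unname(ci[1, ]), ci_hi = unname(ci[2, ])),
      table = table(reference = cat_ref, new = cat_new),
      B = B, thresholds = thresholds),
    class = "nri_result")
}

nri_point <- function(cat_new, cat_ref, times, events, horizon) {
  n <- length(times)
  up <- cat_new > cat_ref
  down <- cat_new < cat_ref
  kmF <- function(idx) {
    if (!any(idx)) return(0)
    km_failure_at(kaplan_meier(times[idx], events[idx]), horizon)$failure
  }
  F_all <- kmF(rep(TRUE, n))
  F_up <- kmF(up); F_down <- kmF(down)
  ev <- if (F_all > 0) {
    (sum(up) * F_up - sum(down) * F_down) / (n * F_all)
  } else 0
  ne <- if (F_all < 1) {
    (sum(down) * (1 - F_down) - sum(up) * (1 - F_up)) / (n * (1 - F_all))
  } else 0
  c(overall = ev + ne, events = ev, nonevents = ne)
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf("Categorical NRI (thresholds %s, B = %d bootstraps)\n",
              paste(x$thresholds, collapse = "/"), x$B))
  print(x$estimates)
  invisible(x)
}

#' @rdname categorical_nri
#' @param x An `nri_result`.
#' @param ... Unused.
#' @method tidy nri_result
#' @export
tidy.nri_result <- function(x, ...) x$estimates
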