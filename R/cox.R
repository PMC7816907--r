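#' Single-covariate Cox proportional hazards fit
#'
#' Fits `Surv(times, events) ~ x` by partial likelihood with the Efron tie
#' correction (robust for heavily tied quarterly follow-up data), Newton-
#' Raphson to tolerance 1e-9 with at most 50 iterations, standard error from
#' the observed information, and a Wald 95% CI. The maximisation is delegated
#' to [survival::coxph()]. Used for the calibration slope (covariate = linear
#' predictor; slope significantly below 1 indicates overfitting of the model
#' on new data), for the high/low triage hazard ratio, and for converting
#' comparator markers to absolute risks.
#'
#' @param x Numeric covariate (non-constant).
#' @param times Positive follow-up times.
#' @param events Event indicators.
#' @param conf_level Confidence level for the Wald interval.
#' @return A `cox_fit1` object: list with `coefficient`, `se`, `hr`, `ci_lo`,
#'   `ci_hi`, `loglik`, `iter`, `converged`, `n`, `n_events`, and the
#'   underlying `fit`.
#' @export
cox_fit_single <- function(x, times, events, conf_level = 0.95) {
  events <- as_event_int(events)
  check_times_events(times, events)
  if (length(unique(x)) == 1L) stop("covariate is constant", call. = FALSE)
  fit <- survival::coxph(
    survival::Surv(times, events) ~ x,
    ties = "efron",
    control = survival::coxph.control(eps = 1e-9, iter.max = 50))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  if (!is.finite(beta) || !is.finite(se) || se > 1e3 || abs(beta) > 20) {
    stop("Cox fit did not converge (monotone likelihood / complete separation?)",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(coefficient = beta, se = se, hr = exp(beta),
         ci_lo = beta - z * se, ci_hi = beta + z * se,
         loglik = fit$loglik[2], iter = fit$iter,
         converged = fit$iter < 50, n = length(times),
         n_events = sum(events), fit = fit),
    class = "cox_fit1")
}

#' @export
print.cox_fit1 <- function(x, ...) {
  cat(sprintf(
    "Cox fit (Efron ties): coef %.4f (SE %.4f), HR %.3f [%.3f, %.3f], %d events / %d\n",
    x$coefficient, x$se, x$hr, exp(x$ci_lo), exp(x$ci_hi), x$n_events, x$n))
  invisible(x)
}

#' @rdname cox_fit_single
#' @param x A `cox_fit1` object.
#' @param ... Unused.
#' @method tidy cox_fit1
#' @export
tidy.cox_fit1 <- function(x, ...) {
  tibble::tibble(term = "x", estimate = x$coefficient, std.error = x$se,
                 hazard.ratio = x$hr,
                 conf.low = x$ci_lo, conf.high = x$ci_hi)
}

#' @rdname cox_fit_single
#' @method glance cox_fit1
#' @export
glance.cox_fit1 <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, loglik = x$loglik,
                 iter = x$iter, converged = x$converged)
}

#' Convert a risk marker to absolute horizon risks
#'
#' Comparator predictors (age alone; the CHA2DS2-VASc score) are unitless
#' orderings, not probabilities. To categorise them on the same absolute risk
#' scale as a risk model, they are mapped to horizon risks through a
#' single-covariate proportional-hazards fit on the validation data plus the
#' Breslow baseline cumulative hazard at the horizon:
#' \eqn{p_i = 1 - \exp(-H_0(h) e^{\beta x_i})}.
#'
#' @param marker Numeric marker.
#' @param times,events Follow-up outcome.
#' @param horizon Horizon (same units as `times`).
#' @return Numeric vector of absolute risks at the horizon.
#' @export
marker_to_risk <- function(marker, times, events, horizon = 5) {
  fit <- cox_fit_single(marker, times, events)
  bh <- survival::basehaz(fit$fit, centered = FALSE)
  idx <- findInterval(horizon, bh$time)
  H0 <- if (idx == 0L) 0 else bh$hazard[idx]
  1 - exp(-H0 * exp(fit$coefficient * marker))
}
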