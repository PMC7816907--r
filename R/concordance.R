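#' Harrell's concordance index for censored data
#'
#' A pair of patients is usable when the shorter observed time is an event
#' (including the case of an event tied with a censoring time, where the
#' censored patient is known to have survived at least as long). A usable
#' pair is concordant when the patient with the earlier event has the higher
#' marker; tied markers count 1/2. Pairs of events at identical times are not
#' usable. The confidence interval is a seeded nonparametric bootstrap over
#' patients (percentile method).
#'
#' @param marker Numeric risk marker (any monotone risk ordering: predicted
#'   risk, linear predictor, age, an integer score...).
#' @param times Positive follow-up times.
#' @param events Event indicators.
#' @param ci Compute a bootstrap confidence interval?
#' @param B Number of bootstrap resamples (default 200).
#' @param seed Seed for the bootstrap.
#' @param conf_level Confidence level.
#' @return Tibble with `c`, `ci_lo`, `ci_hi`, `n`, `n_events`, `usable_pairs`.
#' @export
harrell_c <- function(marker, times, events, ci = TRUE, B = 200L,
                      seed = 20140101, conf_level = 0.95) {
  events <- as_event_int(events)
  check_times_events(times, events)
  if (length(marker) != length(times)) {
    stop("`marker` must match `times` in length", call. = FALSE)
  }
  res <- concordance_point(marker, times, events, warn = TRUE)
  if (res$pairs == 0) stop("no usable pairs for concordance", call. = FALSE)
  lo <- hi <- NA_real_
  if (ci) {
    n <- length(times)
    cs <- withr_seed(seed, {
      vapply(seq_len(B), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        r <- concordance_point(marker[idx], times[idx], events[idx])
        if (r$pairs == 0) NA_real_ else r$concordant / r$pairs
      }, numeric(1))
    })
    alpha <- (1 - conf_level) / 2
    qs <- stats::quantile(cs, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  tibble::tibble(c = res$concordant / res$pairs, ci_lo = lo, ci_hi = hi,
                 n = length(times), n_events = sum(events),
                 usable_pairs = res$pairs)
}

# Pair counting in O(n * d): loop over event times in increasing order and
# compare each event's marker against its comparison set (all longer times,
# plus censored times tied with the event).
concordance_point <- function(marker, times, events, warn = FALSE) {
  if (warn && length(unique(marker)) == 1L) {
    warning("constant marker: concordance is 0.5 by convention", call. = FALSE)
  }
  ord <- order(times)
  t_s <- times[ord]; e_s <- events[ord]; m_s <- marker[ord]
  n <- length(t_s)
  concordant <- 0
  pairs <- 0
  for (i in which(e_s == 1L)) {
    later <- t_s > t_s[i] | (t_s == t_s[i] & e_s == 0L)
    if (!any(later)) next
    mi <- m_s[i]; mj <- m_s[later]
    pairs <- pairs + length(mj)
    concordant <- concordant + sum(mi > mj) + 0.5 * sum(mi == mj)
  }
  list(concordant = concordant, pairs = pairs)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
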