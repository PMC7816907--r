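# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# O(n^2) pair enumeration for Harrell's C: usable pair = shorter time is an
# event (or event tied with a censoring); concordant = earlier event has the
# higher marker; marker ties count 1/2.
oracle_concordance <- function(marker, times, events) {
  n <- length(times)
  conc <- 0; pairs <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    usable <- (events[i] == 1 && times[i] < times[j]) ||
      (events[i] == 1 && events[j] == 0 && times[i] == times[j])
    if (!usable) next
    pairs <- pairs + 1
    if (marker[i] > marker[j]) conc <- conc + 1
    else if (marker[i] == marker[j]) conc <- conc + 0.5
  }
  conc / pairs
}

# brute-force product-limit estimate at each distinct event time
oracle_km_curve <- function(times, events) {
  ts <- sort(unique(times))
  surv <- numeric(length(ts))
  s <- 1
  for (k in seq_along(ts)) {
    at_risk <- sum(times >= ts[k])
    d <- sum(times == ts[k] & events == 1)
    if (at_risk > 0) s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  list(time = ts, survival = surv)
}

# Efron log partial likelihood, written from the definition
oracle_efron_loglik <- function(beta, x, times, events) {
  ll <- 0
  for (t in unique(times[events == 1])) {
    D <- which(times == t & events == 1)
    R <- which(times >= t)
    d <- length(D)
    sumD <- sum(exp(beta * x[D]))
    sumR <- sum(exp(beta * x[R]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1L) {
      ll <- ll - log(sumR - (l / d) * sumD)
    }
  }
  ll
}

oracle_cox_coef <- function(x, times, events, interval = c(-8, 8)) {
  stats::optimize(function(b) oracle_efron_loglik(b, x, times, events),
                  interval = interval, maximum = TRUE, tol = 1e-10)$maximum
}

# closed-form categorical NRI from the cross-tabulation, uncensored data only
oracle_nri_uncensored <- function(cat_new, cat_ref, events) {
  stopifnot(all(events %in% c(0, 1)))
  up <- cat_new > cat_ref; down <- cat_new < cat_ref
  ev <- events == 1
  nri_e <- (sum(up & ev) - sum(down & ev)) / sum(ev)
  nri_ne <- (sum(down & !ev) - sum(up & !ev)) / sum(!ev)
  c(overall = nri_e + nri_ne, events = nri_e, nonevents = nri_ne)
}

# random censored survival fixture
random_fixture <- function(n, seed, tie_prob = 0.3) {
  set.seed(seed)
  times <- ceiling(stats::rexp(n, 0.4) * 4) / 4 # quarterly ties
  if (tie_prob == 0) times <- stats::rexp(n, 0.4) + 0.01
  events <- stats::rbinom(n, 1, 0.6)
  marker <- stats::rnorm(n) + events * 0.5
  list(marker = marker, times = times, events = events)
}
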