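# Internal helpers shared across modules.

invlogit <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

#' @keywords internal
#' @noRd
stop_missing_cols <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(data)
}

# Quantile of a normal truncated below at `lower`; monotone in `mean`, so it
# supports common-random-number calibration of the location parameter.
qtruncnorm_lower <- function(p, mean, sd, lower) {
  p0 <- stats::pnorm((lower - mean) / sd)
  mean + sd * stats::qnorm(p0 + p * (1 - p0))
}

as_event_int <- function(event) {
  if (is.logical(event)) return(as.integer(event))
  ev <- as.integer(event)
  if (!all(ev %in% c(0L, 1L))) stop("`event` must be logical or 0/1", call. = FALSE)
  ev
}

check_times_events <- function(times, events) {
  if (length(times) != length(events)) {
    stop("`times` and `events` must have the same length", call. = FALSE)
  }
  if (length(times) == 0L) stop("empty survival input", call. = FALSE)
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("`times` must be positive and finite", call. = FALSE)
  }
  invisible(NULL)
}
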