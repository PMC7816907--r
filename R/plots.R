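#' Plot a calibration table
#'
#' Observed (Kaplan-Meier, with Greenwood CI brackets) versus mean predicted
#' risk per group; points above the identity line mark risk underestimation,
#' points below overestimation.
#'
#' @param object A [calibration_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot calibration_table
#' @export
autoplot.calibration_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$risk_mean, y = .data$km_failure)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Mean predicted risk",
                  y = sprintf("Observed %g-year incidence (KM)",
                              attr(object, "horizon")),
                  title = "Calibration by risk group") +
    ggplot2::theme_minimal()
}

#' Plot a Kaplan-Meier curve as a failure function
#'
#' @param object A [kaplan_meier()] curve.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$failure)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Years", y = "Cumulative incidence") +
    ggplot2::theme_minimal()
}

#' Plot risk-category stratified failure curves
#'
#' @param object A [stratified_km()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stratified_km
#' @export
autoplot.stratified_km <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$failure,
                               colour = .data$category)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Years", y = "Cumulative AF incidence",
                  colour = "Predicted risk") +
    ggplot2::theme_minimal()
}

#' Plot a triage sensitivity curve
#'
#' Sensitivity (share of observed AF cases among the screened) and the share
#' of patients screened, as step functions of the risk cut-off.
#'
#' @param curve Output of [sensitivity_curve()].
#' @return A ggplot.
#' @export
plot_sensitivity_curve <- function(curve) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(curve, pct_high = .data$pct_high / 100),
    c("sensitivity", "pct_high"),
    names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cutoff, y = .data$value,
                                     colour = .data$measure)) +
    ggplot2::geom_step() +
    ggplot2::scale_colour_discrete(
      labels = c(pct_high = "Share screened", sensitivity = "Sensitivity")) +
    ggplot2::labs(x = "Risk cut-off", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
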