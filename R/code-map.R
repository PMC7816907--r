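#' Diagnosis / prescription code mapping
#'
#' Conditions are identified in raw records by diagnosis codes and medication
#' classes by prescription-code prefixes. The default mapping uses broad
#' ICPC-1-style chapter codes for conditions and ATC cardiovascular chapter
#' prefixes for antihypertensives. It is a documented placeholder suitable for
#' synthetic data: studies on real primary-care extracts must supply the
#' operational code lists agreed for their database, since registries differ
#' in how episodes are coded.
#'
#' @param conditions Named list: condition name -> character vector of
#'   diagnosis codes (matched exactly).
#' @param medications Named list: medication class -> character vector of
#'   prescription-code prefixes (matched by `startsWith`).
#' @return An object of class `code_map`.
#' @examples
#' code_map()$conditions$atrial_fibrillation
#' @export
code_map <- function(conditions = NULL, medications = NULL) {
  default_conditions <- list(
    atrial_fibrillation = "K78",
    heart_failure = "K77",
    myocardial_infarction = "K75",
    hypertension = c("K86", "K87"),
    diabetes = "T90",
    stroke = "K90",
    tia = "K89",
    atherosclerosis = "K91",
    angina = "K74"
  )
  default_medications <- list(
    antihypertensive = c("C02", "C03", "C07", "C08", "C09")
  )
  conditions <- utils::modifyList(default_conditions, conditions %||% list())
  medications <- utils::modifyList(default_medications, medications %||% list())
  if (any(lengths(conditions) == 0L) || any(lengths(medications) == 0L)) {
    stop("every code_map entry must have at least one code", call. = FALSE)
  }
  structure(list(conditions = conditions, medications = medications),
            class = "code_map")
}

#' @export
print.code_map <- function(x, ...) {
  cat("code_map:\n  conditions:\n")
  for (nm in names(x$conditions)) {
    cat(sprintf("    %s: %s\n", nm, paste(x$conditions[[nm]], collapse = ", ")))
  }
  cat("  medication prefixes:\n")
  for (nm in names(x$medications)) {
    cat(sprintf("    %s: %s\n", nm, paste(x$medications[[nm]], collapse = ", ")))
  }
  invisible(x)
}
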