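#' The CHARGE-AF 5-year atrial fibrillation risk model
#'
#' Returns the published CHARGE-AF model constants: the eleven covariate
#' coefficients (with their covariate scalings), the 5-year baseline AF-free
#' survival, and the centering constant. The predicted 5-year risk of new AF is
#'
#' \deqn{p = 1 - S_0^{\exp(\Sigma bX - c)}}
#'
#' where \eqn{\Sigma bX} is the linear predictor over the scaled covariates,
#' \eqn{S_0 = 0.9718412736} the baseline survival and \eqn{c = 12.5815600} the
#' centering constant (the derivation-cohort mean linear predictor).
#'
#' Covariates enter scaled: age/5, height/10 (cm), weight/15 (kg), SBP/20
#' (mm Hg), DBP/10 (mm Hg); ethnicity (Caucasian/white), current smoking,
#' antihypertensive medication use, diabetes, heart failure and myocardial
#' infarction as 0/1 indicators. The DBP coefficient is negative.
#'
#' @param baseline_survival 5-year baseline AF-free survival \eqn{S_0}.
#' @param centering_constant Centering constant subtracted from the linear
#'   predictor before exponentiation.
#' @param coefficients Named numeric vector of the eleven coefficients on the
#'   scaled covariates. Override to swap in a recalibrated variant.
#' @return An object of class `charge_af_model`.
#' @examples
#' m <- charge_af_model()
#' m$coefficients[["heart_failure"]]
#' @export
charge_af_model <- function(baseline_survival = 0.9718412736,
                            centering_constant = 12.5815600,
                            coefficients = NULL) {
  default_coef <- c(
    age_per5 = 0.5083,
    ethnicity_white = 0.46491,
    height_per10 = 0.2478,
    weight_per15 = 0.1155,
    sbp_per20 = 0.1972,
    dbp_per10 = -0.1013,
    smoking = 0.35931,
    antihypertensive = 0.34889,
    diabetes = 0.23666,
    heart_failure = 0.70127,
    myocardial_infarction = 0.49659
  )
  coefficients <- coefficients %||% default_coef
  if (!setequal(names(coefficients), names(default_coef))) {
    stop("`coefficients` must cover exactly the 11 CHARGE-AF terms",
         call. = FALSE)
  }
  stopifnot(baseline_survival > 0, baseline_survival < 1)
  structure(
    list(
      coefficients = coefficients[names(default_coef)],
      baseline_survival = baseline_survival,
      centering_constant = centering_constant,
      horizon_years = 5
    ),
    class = "charge_af_model"
  )
}

#' @export
print.charge_af_model <- function(x, ...) {
  cat("CHARGE-AF 5-year AF risk model\n")
  cat(sprintf("  baseline survival S0 = %.10f, centering constant = %.7f\n",
              x$baseline_survival, x$centering_constant))
  print(round(x$coefficients, 5))
  invisible(x)
}

# Scaled covariate matrix in model-coefficient order, one column per term.
# Used by both the linear predictor and the contribution decomposition so the
# two cannot drift apart.
charge_af_terms <- function(data, model) {
  cols <- c("age", "ethnicity_white", "height", "weight", "sbp", "dbp",
            "smoking", "antihypertensive", "diabetes", "heart_failure",
            "myocardial_infarction")
  stop_missing_cols(data, cols, "cohort data")
  cbind(
    age_per5 = data$age / 5,
    ethnicity_white = as.numeric(data$ethnicity_white),
    height_per10 = data$height / 10,
    weight_per15 = data$weight / 15,
    sbp_per20 = data$sbp / 20,
    dbp_per10 = data$dbp / 10,
    smoking = as.numeric(data$smoking),
    antihypertensive = as.numeric(data$antihypertensive),
    diabetes = as.numeric(data$diabetes),
    heart_failure = as.numeric(data$heart_failure),
    myocardial_infarction = as.numeric(data$myocardial_infarction)
  )
}

#' CHARGE-AF linear predictor
#'
#' Computes \eqn{\Sigma bX} for every row of a cohort table. All eleven
#' covariates must be present and non-missing: the model is only defined for
#' complete cases, and missing measurements raise an error rather than being
#' silently zero-filled.
#'
#' @param data Data frame with columns `age`, `ethnicity_white`, `height`,
#'   `weight`, `sbp`, `dbp`, `smoking`, `antihypertensive`, `diabetes`,
#'   `heart_failure`, `myocardial_infarction`.
#' @param model A [charge_af_model()].
#' @return Numeric vector of linear predictors, one per row.
#' @examples
#' pt <- tibble::tibble(age = 60, ethnicity_white = TRUE, height = 170,
#'                      weight = 80, sbp = 130, dbp = 80, smoking = FALSE,
#'                      antihypertensive = FALSE, diabetes = FALSE,
#'                      heart_failure = FALSE, myocardial_infarction = FALSE)
#' charge_af_lp(pt)
#' @export
charge_af_lp <- function(data, model = charge_af_model()) {
  x <- charge_af_terms(data, model)
  if (anyNA(x)) {
    bad <- unique(colnames(x)[which(is.na(x), arr.ind = TRUE)[, 2]])
    stop(sprintf(
      "incomplete case(s): missing values in %s; CHARGE-AF requires all four body measurements (no zero-fill)",
      paste(bad, collapse = ", ")), call. = FALSE)
  }
  drop(x %*% model$coefficients)
}

#' CHARGE-AF predicted 5-year risk from a linear predictor
#'
#' Applies the baseline-survival power form
#' \eqn{1 - S_0^{\exp(lp - c)}}. Strictly increasing in `lp` and strictly
#' inside (0, 1) for finite `lp`.
#'
#' @param lp Numeric vector of linear predictors.
#' @param model A [charge_af_model()].
#' @return Numeric vector of 5-year risks.
#' @examples
#' charge_af_risk(charge_af_model()$centering_constant)  # 1 - S0
#' @export
charge_af_risk <- function(lp, model = charge_af_model()) {
  if (any(!is.finite(lp))) stop("`lp` must be finite", call. = FALSE)
  1 - model$baseline_survival^exp(lp - model$centering_constant)
}

#' CHA2DS2-VASc stroke risk score
#'
#' Integer score in 0..9: congestive heart failure (1), hypertension (1),
#' age >= 75 (2) or 65-74 (1), diabetes (1), prior stroke or TIA (2), vascular
#' disease (1), female sex (1). Vascular disease here is the disjunction of
#' myocardial infarction, atherosclerotic peripheral/arterial disease and
#' angina flags; its operationalisation against diagnosis codes lives in the
#' [code_map()] and is configurable.
#'
#' @param data Data frame with columns `sex` (`"male"`/`"female"`), `age`,
#'   `heart_failure`, `hypertension`, `diabetes`, `stroke`, `tia`, and the
#'   vascular-disease component columns.
#' @param vascular_cols Character vector of logical columns whose disjunction
#'   defines vascular disease.
#' @return Integer vector of scores.
#' @examples
#' cha2ds2_vasc(tibble::tibble(sex = "female", age = 76, heart_failure = FALSE,
#'   hypertension = TRUE, diabetes = TRUE, stroke = FALSE, tia = FALSE,
#'   myocardial_infarction = FALSE, atherosclerosis = FALSE, angina = FALSE))
#' @export
cha2ds2_vasc <- function(data,
                         vascular_cols = c("myocardial_infarction",
                                           "atherosclerosis", "angina")) {
  stop_missing_cols(
    data,
    c("sex", "age", "heart_failure", "hypertension", "diabetes",
      "stroke", "tia", vascular_cols),
    "cohort data")
  vascular <- Reduce(`|`, lapply(vascular_cols, function(cl) as.logical(data[[cl]])))
  age_pts <- ifelse(data$age >= 75, 2L, ifelse(data$age >= 65, 1L, 0L))
  score <- as.integer(data$heart_failure) +
    as.integer(data$hypertension) +
    age_pts +
    as.integer(data$diabetes) +
    2L * as.integer(data$stroke | data$tia) +
    as.integer(vascular) +
    as.integer(data$sex == "female")
  as.integer(score)
}

#' Assign predicted risks to ordered categories
#'
#' Default thresholds 2.5% and 5% give the low / intermediate / high categories
#' used for stratified calibration and reclassification. The intermediate
#' interval is closed on both sides ("2.5%-5%") while the outer categories are
#' strict ("<2.5%", ">5%"): a risk exactly at the first threshold moves up out
#' of `low`, and a risk exactly at any later threshold stays below it, so
#' 0.025 and 0.05 are both `intermediate` under the defaults.
#'
#' @param risk Numeric vector of probabilities.
#' @param thresholds Strictly increasing probabilities; `k` thresholds give
#'   `k + 1` categories.
#' @param labels Optional category labels; defaults to
#'   `low/intermediate/high` for two thresholds, `cat1..cat(k+1)` otherwise.
#' @return Ordered factor of categories.
#' @examples
#' categorize_risk(c(0.024, 0.025, 0.05, 0.051))
#' @export
categorize_risk <- function(risk, thresholds = c(0.025, 0.05), labels = NULL) {
  if (length(thresholds) == 0L) stop("`thresholds` must be non-empty", call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE) ||
      any(thresholds <= 0) || any(thresholds >= 1)) {
    stop("`thresholds` must be strictly increasing within (0, 1)", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- if (length(thresholds) == 2L) {
      c("low", "intermediate", "high")
    } else {
      paste0("cat", seq_len(length(thresholds) + 1L))
    }
  }
  # bins (t_k, t_{k+1}]; a value exactly at the first threshold moves up
  idx <- findInterval(risk, thresholds, left.open = TRUE) + 1L
  idx[risk == thresholds[1]] <- 2L
  factor(labels[idx], levels = labels, ordered = TRUE)
}

#' Append CHARGE-AF and CHA2DS2-VASc scores to a cohort table
#'
#' Adds the columns `charge_af_lp`, `charge_af_risk5y`, `charge_af_category`,
#' `cha2ds2vasc` and `cha2ds2vasc_ge2`. Rows with any missing CHARGE-AF
#' measurement get `NA` for the CHARGE-AF columns (the model is undefined for
#' incomplete cases); CHA2DS2-VASc and age are always available.
#'
#' @param data Cohort data frame (see [charge_af_lp()] and [cha2ds2_vasc()]
#'   for required columns).
#' @param model A [charge_af_model()].
#' @param thresholds Risk-category thresholds, see [categorize_risk()].
#' @return The input with score columns appended.
#' @export
score_cohort <- function(data, model = charge_af_model(),
                         thresholds = c(0.025, 0.05)) {
  complete <- stats::complete.cases(
    data[, c("height", "weight", "sbp", "dbp")])
  lp <- rep(NA_real_, nrow(data))
  if (any(complete)) lp[complete] <- charge_af_lp(data[complete, , drop = FALSE], model)
  risk <- ifelse(is.na(lp), NA_real_, charge_af_risk(ifelse(is.na(lp), 0, lp), model))
  vasc <- cha2ds2_vasc(data)
  dplyr::mutate(
    tibble::as_tibble(data),
    charge_af_lp = lp,
    charge_af_risk5y = risk,
    charge_af_category = categorize_risk(.data$charge_af_risk5y, thresholds),
    cha2ds2vasc = vasc,
    cha2ds2vasc_ge2 = vasc >= 2L
  )
}

#' Per-variable contribution to the CHARGE-AF linear predictor by risk stratum
#'
#' For successive strata of predicted baseline risk, multiplies the stratum
#' mean of each scaled covariate by its coefficient. Row sums over the eleven
#' terms reproduce the stratum mean linear predictor exactly, so the table
#' decomposes where risk differences between strata come from (in this
#' population, dominated by age).
#'
#' @param data Scored cohort (complete cases) with the CHARGE-AF covariate
#'   columns.
#' @param model A [charge_af_model()].
#' @param strata_breaks Increasing interior risk cut points defining the
#'   strata, e.g. `c(0.025, 0.05, 0.10)`.
#' @return Tibble with one row per non-empty stratum: `stratum`, `n`, one
#'   column per model term, and `lp_mean`.
#' @export
contribution_decomposition <- function(data, model = charge_af_model(),
                                       strata_breaks = c(0.025, 0.05, 0.10)) {
  lp <- charge_af_lp(data, model)
  risk <- charge_af_risk(lp, model)
  cat <- categorize_risk(risk, strata_breaks,
                         labels = paste0("stratum", seq_len(length(strata_breaks) + 1L)))
  x <- charge_af_terms(data, model)
  contrib <- sweep(x, 2L, model$coefficients, `*`)
  levels_present <- levels(cat)[levels(cat) %in% as.character(unique(cat))]
  if (length(levels_present) < length(levels(cat))) {
    warning("empty risk stratum(s) omitted from decomposition", call. = FALSE)
  }
  rows <- lapply(levels_present, function(lv) {
    idx <- which(cat == lv)
    means <- colMeans(contrib[idx, , drop = FALSE])
    tibble::tibble(stratum = lv, n = length(idx), !!!as.list(means),
                   lp_mean = mean(lp[idx]))
  })
  dplyr::bind_rows(rows)
}
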