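Package: chargeaf
Title: Validation of the CHARGE-AF Atrial Fibrillation Risk Model in Routine Care Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for external validation of the CHARGE-AF 5-year atrial
    fibrillation risk equation in primary-care style electronic health record
    cohorts. Computes the CHARGE-AF linear predictor and absolute 5-year risk,
    the CHA2DS2-VASc score, and risk categories; derives analysis cohorts from
    raw EHR-like records (baseline covariate extraction, eligibility filtering,
    complete-case identification); resolves censored time-to-event outcomes
    from quarterly registration data; and implements the censoring-aware
    validation statistics used in prognostic model validation (Harrell's
    C-statistic, calibration tables with a Nam-D'Agostino style goodness-of-fit
    test, calibration slope, categorical net reclassification improvement, and
    screening triage tables over risk cut-offs). A calibrated synthetic cohort
    generator emulates the covariate marginals, informative measurement
    missingness, event rates, and quarterly-registration censoring of a Dutch
    primary-care validation population so the full pipeline runs without any
    licensed data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
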