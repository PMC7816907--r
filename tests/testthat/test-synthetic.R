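test_that("generation is bit-identical under a fixed config and seed", {
  a <- generate_cohort(1200, seed = 99)
  b <- generate_cohort(1200, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "provenance"), attr(b, "provenance"))
  d <- generate_cohort(1200, seed = 100)
  expect_false(identical(a$age, d$age))
  # provenance hash responds to config changes
  e <- generate_cohort(1200, af_cohort_config(female_frac = 0.4), seed = 99)
  expect_false(identical(attr(a, "provenance")$hash, attr(e, "provenance")$hash))
})

test_that("complete-case marginals hit their calibration targets", {
  coh <- generate_cohort(40000, seed = 101)
  cc <- coh[coh$complete, ]
  cfg <- af_cohort_config()
  expect_equal(mean(coh$complete), cfg$complete_frac, tolerance = 0.01)
  expect_equal(mean(cc$age), cfg$age_mean, tolerance = 0.25)
  expect_equal(mean(cc$sex == "female"), cfg$female_frac, tolerance = 0.02)
  expect_equal(mean(cc$height_full), cfg$height_mean, tolerance = 0.5)
  expect_equal(sd(cc$height_full), cfg$height_sd, tolerance = 0.5)
  expect_equal(mean(cc$sbp_full), cfg$sbp_mean, tolerance = 0.7)
  expect_equal(mean(cc$dbp_full), cfg$dbp_mean, tolerance = 0.5)
  for (nm in names(cfg$prevalence)) {
    expect_equal(mean(cc[[nm]]), unname(cfg$prevalence[[nm]]),
                 tolerance = 0.02, label = nm)
  }
  expect_true(all(cc$age >= 40))
  # true risk equals the model applied to the generated covariates
  expect_equal(cc$true_risk, charge_af_risk(charge_af_lp(cc)),
               tolerance = 1e-12)
})

test_that("missingness is informative in the documented direction", {
  coh <- generate_cohort(30000, seed = 102)
  cnt <- rowSums(coh[, c("antihypertensive", "hypertension", "diabetes",
                         "heart_failure", "myocardial_infarction", "stroke",
                         "tia", "atherosclerosis", "angina")])
  expect_gt(mean(cnt[coh$complete]), mean(cnt[!coh$complete]))
  expect_gt(mean(coh$age[coh$complete]), mean(coh$age[!coh$complete]))
  # incomplete cases lack 1..4 measurements but keep the generating truth
  inc <- coh[!coh$complete, ]
  n_missing <- rowSums(is.na(inc[, c("height", "weight", "sbp", "dbp")]))
  expect_true(all(n_missing >= 1 & n_missing <= 4))
  expect_false(anyNA(inc[, c("height_full", "weight_full", "sbp_full",
                             "dbp_full")]))
  # complete cases are untouched
  comp <- coh[coh$complete, ]
  expect_identical(comp$height, comp$height_full)
})

test_that("slope-free missingness collapses to missing completely at random", {
  cfg <- af_cohort_config(miss_count_slope = 0, miss_age_slope = 0)
  coh <- generate_cohort(20000, cfg, seed = 103)
  expect_equal(mean(coh$complete), 0.172, tolerance = 0.012)
  cnt <- rowSums(coh[, c("antihypertensive", "hypertension", "diabetes",
                         "heart_failure", "myocardial_infarction", "stroke",
                         "tia", "atherosclerosis", "angina")])
  expect_equal(mean(cnt[coh$complete]), mean(cnt[!coh$complete]),
               tolerance = 0.08)
})

test_that("zero age slope makes a comorbidity independent of age", {
  slopes <- af_cohort_config()$age_slopes
  slopes["diabetes"] <- 0
  coh <- generate_cohort(30000, af_cohort_config(age_slopes = slopes),
                         seed = 104)
  dm <- coh$diabetes
  expect_lt(abs(cor(coh$age, as.numeric(dm))), 0.02)
  expect_equal(mean(dm[coh$complete]), 0.427, tolerance = 0.025)
})

test_that("event times follow the per-patient hazards they were drawn from", {
  # with no censoring the within-horizon event fraction converges to the
  # mean generating risk
  cfg <- af_cohort_config(dropout_quarterly = 0, hazard_multiplier = 1)
  coh <- generate_cohort(50000, cfg, seed = 105)
  expect_lt(abs(mean(coh$af_time <= 5) - mean(coh$event_risk5y)), 0.005)
  expect_equal(mean(coh$event), mean(coh$af_time <= 5), tolerance = 1e-12)
  # multiplier 1: generating risk is the model risk itself
  expect_equal(coh$event_risk5y, coh$true_risk, tolerance = 1e-12)
  # hazard identity at the centering constant, printed-constant algebra
  lam_expected <- -log(0.9718412736) / 5
  p0 <- 1 - 0.9718412736
  expect_equal(-log(1 - p0) / 5, lam_expected, tolerance = 1e-15)
})

test_that("dropout calibration hits the follow-up target and clusters by practice when enabled", {
  coh <- generate_cohort(30000, seed = 106)
  cc <- coh[coh$complete, ]
  expect_equal(mean(cc$time_years), 3.5, tolerance = 0.02)
  expect_true(all(coh$time_years > 0 & coh$time_years <= 5))
  expect_true(all(coh$event == (coh$censor_reason == "af_event")))
  # no dropout: follow-up is min(event time, horizon)
  cfg0 <- af_cohort_config(dropout_quarterly = 0)
  coh0 <- generate_cohort(5000, cfg0, seed = 107)
  expect_equal(coh0$time_years, pmin(coh0$af_time, 5), tolerance = 1e-12)
  # practice-level dropout produces practice-clustered loss dates
  cfgp <- af_cohort_config(practice_dropout_quarterly = 0.02, n_practices = 40)
  cohp <- generate_cohort(12000, cfgp, seed = 108)
  lost <- cohp[cohp$censor_reason == "lost_to_followup" &
                 !is.na(cohp$loss_quarter), ]
  fit <- stats::aov(loss_quarter ~ practice_id, data = lost)
  expect_lt(summary(fit)[[1]][["Pr(>F)"]][1], 1e-6)
})

test_that("raising a calibration target raises the solved parameter", {
  base <- generate_cohort(8000, seed = 109)
  hi_inc <- generate_cohort(
    8000, af_cohort_config(target_cum_incidence = 0.08), seed = 109)
  expect_gt(attr(hi_inc, "hazard_multiplier"), attr(base, "hazard_multiplier"))
  lo_fu <- generate_cohort(
    8000, af_cohort_config(target_mean_followup = 2.5), seed = 109)
  expect_gt(attr(lo_fu, "dropout_quarterly"), attr(base, "dropout_quarterly"))
  hi_cf <- generate_cohort(
    8000, af_cohort_config(complete_frac = 0.3), seed = 109)
  expect_gt(mean(hi_cf$complete), mean(base$complete))
})

test_that("well-specified cohorts look like the study conditions they emulate", {
  coh <- generate_cohort(40000, seed = 110)
  cc <- coh[coh$complete, ]
  # discrimination of the generating risk: strong, and above age alone
  set.seed(111)
  idx <- sample(nrow(cc), 5000)
  c_true <- harrell_c(cc$true_risk[idx], cc$time_years[idx], cc$event[idx],
                      ci = FALSE)$c
  c_age <- harrell_c(cc$age[idx], cc$time_years[idx], cc$event[idx],
                     ci = FALSE)$c
  expect_gt(c_true, 0.70)
  expect_lt(c_true, 0.90)
  expect_gt(c_age, 0.5)
  expect_gt(c_true, c_age)
  # calibration slope of the generating linear predictor is 1 by construction
  sl <- cox_fit_single(coh$true_lp, coh$time_years, coh$event)
  expect_true(abs(sl$coefficient - 1) < 3 * sl$se)
  # the generating risk is well calibrated: goodness of fit not rejected
  ct <- calibration_table(cc$event_risk5y, cc$time_years, cc$event,
                          min_events = 10)
  expect_gt(nam_dagostino(ct)$p_value, 0.01)
})

test_that("injected slope distortion is recovered by the calibration slope", {
  coh <- generate_cohort(20000, af_cohort_config(lp_slope = 0.69), seed = 112)
  sl <- cox_fit_single(coh$true_lp, coh$time_years, coh$event)
  expect_equal(sl$coefficient, 0.69, tolerance = 0.15)
  expect_true(sl$ci_lo < 0.69 + 0.05 && sl$ci_hi > 0.69 - 0.05)
  # and a distortion-free run is materially closer to 1
  coh1 <- generate_cohort(20000, seed = 112)
  sl1 <- cox_fit_single(coh1$true_lp, coh1$time_years, coh1$event)
  expect_gt(sl1$coefficient, sl$coefficient + 0.15)
})

test_that("raw-record emission round-trips through the extraction pipeline", {
  coh <- generate_cohort(700, seed = 113)
  rec <- emit_raw_records(coh)
  bl <- extract_baseline(rec)
  bl <- bl[match(coh$patient_id, bl$patient_id), ]
  expect_identical(bl$age, as.integer(coh$age))
  expect_identical(bl$sex, coh$sex)
  for (nm in c("height", "weight", "sbp", "dbp")) {
    expect_identical(is.na(bl[[nm]]), is.na(coh[[nm]]), label = nm)
    expect_identical(bl[[nm]][!is.na(bl[[nm]])], coh[[nm]][!is.na(coh[[nm]])],
                     label = nm)
  }
  for (nm in c("smoking", "antihypertensive", "hypertension", "diabetes",
               "heart_failure", "myocardial_infarction", "stroke", "tia",
               "atherosclerosis", "angina")) {
    expect_identical(bl[[nm]], coh[[nm]], label = nm)
  }
  sp <- split_complete_cases(bl)
  expect_setequal(sp$complete$patient_id, coh$patient_id[coh$complete])
  fu <- derive_followup(rec)
  fu <- fu[match(coh$patient_id, fu$patient_id), ]
  expect_identical(fu$event, coh$event)
  expect_identical(fu$censor_reason, coh$censor_reason)
  expect_lt(max(abs(fu$time_years - coh$time_years)), 0.01)
  # patients with masked height emit no height entries
  masked <- coh$patient_id[is.na(coh$height)]
  hm <- rec$measurements[rec$measurements$kind == "height_cm", ]
  expect_length(intersect(masked, hm$patient_id), 0L)
  # decoy entries exist yet closest-to-baseline recovery still matched
  per_kind <- table(rec$measurements$patient_id, rec$measurements$kind)
  expect_gt(max(per_kind[, "sbp_mmHg"]), 1)
})
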