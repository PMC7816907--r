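test_that("concordance equals the O(n^2) pair-enumeration oracle on small fixtures", {
  for (s in 1:8) {
    n <- sample(8:30, 1)
    fx <- random_fixture(n, seed = 700 + s, tie_prob = if (s %% 2) 0.3 else 0)
    got <- harrell_c(fx$marker, fx$times, fx$events, ci = FALSE)
    expect_equal(got$c, oracle_concordance(fx$marker, fx$times, fx$events),
                 tolerance = 1e-12)
  }
})

test_that("concordance agrees with the survival package on untied data", {
  fx <- random_fixture(400, seed = 31, tie_prob = 0)
  got <- harrell_c(fx$marker, fx$times, fx$events, ci = FALSE)
  ref <- survival::concordance(
    survival::Surv(fx$times, fx$events) ~ fx$marker, reverse = TRUE)
  expect_equal(got$c, unname(ref$concordance), tolerance = 1e-10)
})

test_that("concordance limiting behaviour: perfect, anti-perfect, uninformative", {
  tm <- c(5, 4, 3, 2, 1); ev <- rep(1, 5)
  expect_equal(harrell_c(1:5, tm, ev, ci = FALSE)$c, 1)
  expect_equal(harrell_c(5:1, tm, ev, ci = FALSE)$c, 0)
  set.seed(13)
  n <- 2000
  tm2 <- rexp(n); ev2 <- rbinom(n, 1, 0.7); mk <- rnorm(n)
  expect_equal(harrell_c(mk, tm2 + 0.01, ev2, ci = FALSE)$c, 0.5,
               tolerance = 0.03)
  expect_warning(cst <- harrell_c(rep(1, 10), rexp(10) + 0.1,
                                  rbinom(10, 1, 0.8), ci = FALSE),
                 "constant")
  expect_equal(cst$c, 0.5)
  expect_error(harrell_c(1:3, c(1, 2, 3), c(0, 0, 0)), "no usable pairs")
})

test_that("concordance of a marker and its negation sum to one", {
  for (s in 1:4) {
    fx <- random_fixture(40, seed = 800 + s)
    c1 <- harrell_c(fx$marker, fx$times, fx$events, ci = FALSE)$c
    c2 <- harrell_c(-fx$marker, fx$times, fx$events, ci = FALSE)$c
    expect_equal(c1 + c2, 1, tolerance = 1e-12)
  }
})

test_that("bootstrap CI is seeded, reproducible and brackets the estimate", {
  fx <- random_fixture(150, seed = 32)
  a <- harrell_c(fx$marker, fx$times, fx$events, B = 100, seed = 1)
  b <- harrell_c(fx$marker, fx$times, fx$events, B = 100, seed = 1)
  d <- harrell_c(fx$marker, fx$times, fx$events, B = 100, seed = 2)
  expect_identical(a, b)
  expect_false(identical(a$ci_lo, d$ci_lo))
  expect_lte(a$ci_lo, a$c)
  expect_gte(a$ci_hi, a$c)
})

test_that("single-covariate Cox fit matches brute-force likelihood maximisation", {
  # untied fixture of 6 as well as tied quarterly fixtures
  x6 <- c(0, 1, 0, 1, 1, 0)
  t6 <- c(1.1, 2.3, 3.1, 4.7, 5.3, 6.9)
  e6 <- c(1, 1, 0, 1, 0, 1)
  fit <- cox_fit_single(x6, t6, e6)
  expect_equal(fit$coefficient, oracle_cox_coef(x6, t6, e6), tolerance = 1e-6)
  for (s in 1:4) {
    fx <- random_fixture(25, seed = 900 + s)
    x <- round(fx$marker, 1)
    fit <- cox_fit_single(x, fx$times, fx$events)
    expect_equal(fit$coefficient, oracle_cox_coef(x, fx$times, fx$events),
                 tolerance = 1e-6)
  }
})

test_that("Cox fit obeys the reparameterisation identity and errors on degenerate input", {
  fx <- random_fixture(80, seed = 33)
  f1 <- cox_fit_single(fx$marker, fx$times, fx$events)
  f2 <- cox_fit_single(2 * fx$marker, fx$times, fx$events)
  expect_equal(f2$coefficient, f1$coefficient / 2, tolerance = 1e-7)
  expect_equal(f2$hr, exp(f2$coefficient))
  expect_error(cox_fit_single(rep(1, 80), fx$times, fx$events), "constant")
  # complete separation: the separating covariate has monotone likelihood
  tm <- c(1, 2, 3, 10, 11, 12); ev <- c(1, 1, 1, 0, 0, 0)
  expect_error(cox_fit_single(c(5, 5, 5, -5, -5, -5), tm, ev), "converge")
})

test_that("Cox parameter recovery within 2 SE in at least 93 of 100 replicates", {
  set.seed(21)
  hits <- 0
  for (r in 1:100) {
    n <- 400
    x <- rnorm(n)
    tm <- rexp(n, rate = 0.1 * exp(0.7 * x))
    cens <- runif(n, 0, 15)
    fit <- cox_fit_single(x, pmin(tm, cens) + 1e-9, as.integer(tm <= cens))
    hits <- hits + (abs(fit$coefficient - 0.7) <= 2 * fit$se)
  }
  expect_gte(hits, 93)
})

test_that("tidy and glance expose the Cox fit in broom form", {
  fx <- random_fixture(60, seed = 34)
  fit <- cox_fit_single(fx$marker, fx$times, fx$events)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "hazard.ratio",
                     "conf.low", "conf.high"))
  expect_equal(td$hazard.ratio, exp(td$estimate))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_identical(gl$n, 60L)
})

test_that("calibration table groups are ordered, exhaustive and reproducible", {
  set.seed(41)
  n <- 500
  risks <- runif(n, 0.01, 0.4)
  tm <- rexp(n, 0.05) + 0.01
  ev <- rbinom(n, 1, 0.3)
  ct <- calibration_table(risks, tm, ev)
  expect_identical(sum(ct$n), as.integer(n))
  expect_true(!is.unsorted(ct$risk_mean))
  ct2 <- calibration_table(risks, tm, ev)
  expect_identical(ct, ct2)
  # equal risks: grouping is forced by the id tie-break; observed equals the
  # overall KM in expectation, exactly when groups share the km estimate
  r0 <- rep(0.1, 60)
  ct3 <- calibration_table(r0, tm[1:60], ev[1:60], n_groups = 3)
  expect_identical(sum(ct3$n), 60L)
  expect_true(all(ct3$risk_mean == 0.1))
})

test_that("well-calibrated simulation puts observed near predicted in every decile", {
  set.seed(42)
  n <- 50000
  risks <- pmin(exp(rnorm(n, log(0.05), 0.5)), 0.8)
  ev <- rbinom(n, 1, risks)
  tm <- ifelse(ev == 1, runif(n, 0.01, 5), 5)
  ct <- calibration_table(risks, tm, ev)
  expect_lt(max(abs(ct$km_failure - ct$risk_mean)), 0.01)
  # doubled hazard: observed exceeds predicted in every decile
  ev2 <- rbinom(n, 1, pmin(2 * risks, 1))
  tm2 <- ifelse(ev2 == 1, runif(n, 0.01, 5), 5)
  ct2 <- calibration_table(risks, tm2, ev2)
  expect_true(all(ct2$km_failure > ct2$risk_mean))
})

test_that("sparse-event groups can be merged to a minimum event count", {
  set.seed(43)
  n <- 4000
  risks <- pmin(exp(rnorm(n, log(0.03), 1)), 0.8)
  ev <- rbinom(n, 1, risks)
  tm <- ifelse(ev == 1, runif(n, 0.01, 5), 5)
  ct <- calibration_table(risks, tm, ev, min_events = 10)
  expect_true(all(ct$n_events >= 10))
  expect_identical(sum(ct$n), as.integer(n))
  expect_true(!is.unsorted(ct$risk_mean))
})

test_that("goodness-of-fit statistic matches the two-group hand example", {
  tab <- structure(
    tibble::tibble(group = 1:2, n = c(100L, 100L), n_events = c(15L, 25L),
                   risk_mean = c(0.1, 0.2), km_failure = c(0.15, 0.25),
                   km_var = c(0.15 * 0.85 / 100, 0.25 * 0.75 / 100),
                   ci_lo = NA_real_, ci_hi = NA_real_),
    class = c("calibration_table", class(tibble::tibble())), horizon = 5)
  nd <- nam_dagostino(tab, variance = "binomial", df = "G-1")
  # 100*0.0025/0.09 + 100*0.0025/0.16 = 4.3402778
  expect_equal(nd$chisq, 4.3402777777777777, tolerance = 1e-10)
  expect_identical(nd$df, 1L)
  # perfect agreement gives chi-square 0, p = 1 under either variant
  tab0 <- tab; tab0$km_failure <- tab0$risk_mean
  expect_equal(nam_dagostino(tab0, variance = "binomial")$chisq, 0)
  expect_equal(nam_dagostino(tab0)$p_value, 1)
})

test_that("goodness-of-fit statistic is invariant to group relabelling", {
  set.seed(44)
  risks <- runif(300, 0.05, 0.3)
  ev <- rbinom(300, 1, risks)
  tm <- ifelse(ev == 1, runif(300, 0.01, 5), 5)
  ct <- calibration_table(risks, tm, ev, n_groups = 5)
  shuffled <- ct[sample(nrow(ct)), ]
  class(shuffled) <- class(ct)
  expect_equal(nam_dagostino(shuffled)$chisq, nam_dagostino(ct)$chisq)
})

test_that("self-comparison NRI is exactly zero with a CI containing zero", {
  set.seed(51)
  n <- 300
  risks <- runif(n, 0.005, 0.2)
  tm <- rexp(n, 0.03) + 0.01
  ev <- rbinom(n, 1, 0.2)
  nri <- categorical_nri(risks, risks, times = tm, events = ev, B = 50, seed = 1)
  expect_identical(nri$estimates$estimate, c(0, 0, 0))
  expect_lte(nri$estimates$ci_lo[1], 0)
  expect_gte(nri$estimates$ci_hi[1], 0)
})

test_that("NRI equals the closed-form contingency enumeration without censoring", {
  for (s in 1:5) {
    set.seed(1000 + s)
    n <- 50
    risk_new <- runif(n, 0.001, 0.25)
    risk_ref <- pmin(pmax(risk_new + rnorm(n, 0, 0.03), 0.001), 0.3)
    ev <- rbinom(n, 1, 0.4)
    if (sum(ev) == 0 || sum(ev) == n) next
    tm <- ifelse(ev == 1, runif(n, 0.1, 4.9), 5) # everyone followed to horizon
    nri <- categorical_nri(risk_new, risk_ref, times = tm, events = ev,
                           B = 10, seed = 2)
    orc <- oracle_nri_uncensored(
      as.integer(categorize_risk(risk_new)),
      as.integer(categorize_risk(risk_ref)), ev)
    expect_equal(nri$estimates$estimate, unname(orc), tolerance = 1e-12)
  }
})

test_that("NRI decomposition identity holds and favours the better model", {
  coh <- generate_cohort(10000, seed = 61)
  cc <- coh[coh$complete, ]
  true_risk <- cc$event_risk5y
  set.seed(62)
  noisy <- plogis(qlogis(true_risk) + rnorm(nrow(cc), 0, 1))
  nri <- categorical_nri(true_risk, noisy, times = cc$time_years,
                         events = cc$event, B = 50, seed = 63)
  est <- nri$estimates$estimate
  expect_equal(est[1], est[2] + est[3], tolerance = 1e-12)
  expect_gt(est[1], 0) # generating risk beats its noisy copy
})

test_that("degenerate single-cell occupancy warns and returns zero NRI", {
  tm <- rexp(40) + 0.01; ev <- rbinom(40, 1, 0.5)
  expect_warning(
    nri <- categorical_nri(rep(0.01, 40), rep(0.012, 40), times = tm,
                           events = ev, B = 5, seed = 1),
    "degenerate")
  expect_identical(nri$estimates$estimate[1], 0)
})

test_that("marker-to-risk conversion is monotone and anchored to observed incidence", {
  coh <- generate_cohort(8000, seed = 71)
  cc <- coh[coh$complete, ]
  r_age <- marker_to_risk(cc$age, cc$time_years, cc$event)
  expect_true(all(r_age >= 0 & r_age < 1))
  expect_true(!is.unsorted(r_age[order(cc$age)]))
  # mean converted risk is near the KM cumulative incidence
  kmf <- km_failure_at(kaplan_meier(cc$time_years, cc$event), 5)$failure
  expect_lt(abs(mean(r_age) - kmf), 0.012)
})

test_that("stratified KM curves are ordered by risk category at the horizon", {
  coh <- generate_cohort(20000, seed = 72)
  cc <- coh[coh$complete, ]
  skm <- stratified_km(cc$event_risk5y, times = cc$time_years,
                       events = cc$event)
  sm <- attr(skm, "summary")
  expect_identical(as.character(sm$category),
                   c("low", "intermediate", "high"))
  expect_true(!is.unsorted(sm$failure_at_horizon))
  # each stratum's observed failure falls inside its own predicted band
  expect_lt(sm$failure_at_horizon[1], 0.025 + 2 * sm$se[1])
  expect_true(sm$failure_at_horizon[2] > 0.025 - 2 * sm$se[2] &&
                sm$failure_at_horizon[2] < 0.05 + 2 * sm$se[2])
  expect_gt(sm$failure_at_horizon[3], 0.05 - 2 * sm$se[3])
  # single occupied category equals the global KM
  skm1 <- stratified_km(rep(0.04, nrow(cc)), times = cc$time_years,
                        events = cc$event)
  expect_identical(nrow(attr(skm1, "summary")), 1L)
  expect_equal(attr(skm1, "summary")$failure_at_horizon,
               km_failure_at(kaplan_meier(cc$time_years, cc$event), 5)$failure)
})

test_that("stratified validation report covers strata and predictor ordering", {
  coh <- generate_cohort(25000, seed = 73)
  cc <- score_cohort(coh[coh$complete, ])
  rep <- stratified_validation(cc, ci = FALSE)
  expect_setequal(unique(rep$predictor), c("charge_af", "cha2ds2vasc", "age"))
  # disjoint strata cover the cohort
  n_all <- rep$n[rep$stratum == "all"][1]
  expect_identical(sum(unique(rep[rep$stratum %in% c("men", "women"), c("stratum", "n")])$n),
                   n_all)
  # model risk discriminates at least as well as age alone in every stratum
  wide <- tidyr::pivot_wider(rep[, c("stratum", "predictor", "c")],
                             names_from = "predictor", values_from = "c")
  expect_true(all(wide$charge_af > wide$age - 0.02))
  # slope and goodness of fit only reported for the model itself
  expect_true(all(is.na(rep$slope[rep$predictor != "charge_af"])))
  expect_true(all(!is.na(rep$slope[rep$predictor == "charge_af"])))
})

test_that("small strata are skipped with a warning", {
  coh <- generate_cohort(3000, seed = 74)
  cc <- score_cohort(coh[coh$complete, ])
  expect_warning(stratified_validation(cc, min_stratum_n = 400, ci = FALSE),
                 "below minimum size")
})
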