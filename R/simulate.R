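#' Configuration for the synthetic EHR cohort generator
#'
#' Defaults emulate the validation population the pipeline was designed for:
#' a primary-care cohort of patients aged 40+ free of AF at baseline, whose
#' complete-case subset (all four body measurements recorded) matches the
#' published baseline table — mean age 65.5 (SD 11.4), 52.5% female, height
#' 170.0 (9.9) cm, weight 82.5 (16.8) kg, SBP 137.3 (16.3), DBP 80.5 (10.5)
#' mm Hg, the listed comorbidity prevalences, a 17.2% complete-case fraction
#' under informative (comorbidity-driven) missingness, a 4.7% cumulative
#' 5-year AF incidence among complete cases, and mean observed follow-up of
#' 3.5 years under quarterly-registration dropout.
#'
#' All of these are *complete-case* calibration targets: the generator solves
#' population-level parameters (age location, comorbidity intercepts,
#' missingness intercepts, hazard multiplier, quarterly dropout probability)
#' so that the complete-case subset hits them; the generated population is
#' correspondingly younger and less comorbid than its complete cases, which
#' is the point of the informative-missingness design.
#'
#' @param age_mean,age_sd,age_min Truncated-normal age parameters (years);
#'   ages are completed years (integers) at baseline.
#' @param female_frac Female fraction.
#' @param height_mean,height_sd,weight_mean,weight_sd Overall marginals;
#'   `sex_height_diff`/`sex_weight_diff` are male-minus-female mean offsets
#'   and `height_weight_cor` the within-sex correlation.
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd,sbp_dbp_cor Blood pressure
#'   marginals (mm Hg) and correlation.
#' @param prevalence Named complete-case target prevalences for the binary
#'   covariates.
#' @param age_slopes Named per-year log-odds slopes of each binary covariate
#'   on age.
#' @param miss_count_slope,miss_age_slope Log-odds slopes of the probability
#'   that all four measurements are recorded, per comorbidity count and per
#'   year of age (missingness is MNAR when nonzero).
#' @param complete_frac Target complete-case fraction.
#' @param target_cum_incidence Target 5-year cumulative AF incidence among
#'   complete cases; drives the solved hazard multiplier.
#' @param hazard_multiplier Fixed multiplier on the generating 5-year risk
#'   (`NULL` = solve to the incidence target).
#' @param lp_slope,lp_shift Miscalibration knobs: the generating linear
#'   predictor is `c + lp_slope * (lp - c) + lp_shift` with `c` the model's
#'   centering constant. Defaults (1, 0) generate from the model itself;
#'   e.g. `lp_slope = 0.69` injects the overfitting pattern a calibration
#'   slope analysis should recover.
#' @param target_mean_followup Target mean observed follow-up (years) among
#'   complete cases.
#' @param dropout_quarterly Fixed per-quarter dropout probability (`NULL` =
#'   solve to the follow-up target).
#' @param practice_dropout_quarterly Per-quarter probability that an entire
#'   practice drops out (0 = off); produces practice-clustered loss dates.
#' @param n_practices Number of practices.
#' @param horizon Observation horizon (years); `n_quarters` follow-up
#'   quarters.
#' @param model The [charge_af_model()] used as generating truth.
#' @return A `af_cohort_config` list.
#' @export
af_cohort_config <- function(
    age_mean = 65.5, age_sd = 11.4, age_min = 40,
    female_frac = 0.525,
    height_mean = 170.0, height_sd = 9.9,
    weight_mean = 82.5, weight_sd = 16.8,
    height_weight_cor = 0.5, sex_height_diff = 13, sex_weight_diff = 12,
    sbp_mean = 137.3, sbp_sd = 16.3, dbp_mean = 80.5, dbp_sd = 10.5,
    sbp_dbp_cor = 0.5,
    prevalence = c(antihypertensive = 0.709, hypertension = 0.665,
                   diabetes = 0.427, heart_failure = 0.042,
                   myocardial_infarction = 0.049, smoking = 0.142,
                   stroke = 0.067, tia = 0.030, atherosclerosis = 0.057,
                   angina = 0.091),
    age_slopes = c(antihypertensive = 0.06, hypertension = 0.07,
                   diabetes = 0.05, heart_failure = 0.09,
                   myocardial_infarction = 0.05, smoking = -0.03,
                   stroke = 0.07, tia = 0.06, atherosclerosis = 0.06,
                   angina = 0.05),
    miss_count_slope = 0.35, miss_age_slope = 0.01, complete_frac = 0.172,
    target_cum_incidence = 0.047, hazard_multiplier = NULL,
    lp_slope = 1, lp_shift = 0,
    target_mean_followup = 3.5, dropout_quarterly = NULL,
    practice_dropout_quarterly = 0, n_practices = 100,
    horizon = 5, n_quarters = 20,
    model = charge_af_model()) {
  cfg <- as.list(environment())
  flags <- names(cfg$prevalence)
  if (!setequal(flags, names(cfg$age_slopes))) {
    stop("`prevalence` and `age_slopes` must name the same covariates",
         call. = FALSE)
  }
  probs <- c(cfg$prevalence, cfg$female_frac, cfg$complete_frac,
             cfg$target_cum_incidence)
  if (any(probs <= 0 | probs >= 1)) {
    stop("all probability parameters must lie strictly in (0, 1)", call. = FALSE)
  }
  if (cfg$target_mean_followup >= cfg$horizon &&
      is.null(cfg$dropout_quarterly)) {
    stop("target mean follow-up must be below the horizon", call. = FALSE)
  }
  structure(cfg, class = "af_cohort_config")
}

# flags entering the comorbidity count that drives missingness (smoking is a
# recorded status, not a morbidity episode)
count_flags <- function() {
  c("antihypertensive", "hypertension", "diabetes", "heart_failure",
    "myocardial_infarction", "stroke", "tia", "atherosclerosis", "angina")
}

# logit of a subset proportion, smoothed so tiny subsets cannot produce +-Inf
slogit <- function(x, m) logit((x * m + 0.5) / (m + 1))

#' Generate baseline covariates
#'
#' Draws ages from a truncated normal (reported as completed years), sex,
#' correlated height/weight with sex-specific offsets, correlated SBP/DBP,
#' and the binary covariates from logistic-in-age models. The age location,
#' the per-covariate intercepts and the missingness intercepts are solved by
#' a deterministic fixed-point iteration (common random numbers) so that the
#' complete-case subset matches the configured targets; the solved values are
#' attached as `attr(, "solved")` and reused by [impose_missingness()].
#'
#' @param n Number of patients.
#' @param config An [af_cohort_config()].
#' @param seed Integer seed; `seed + 1` is reserved for the missingness draw.
#' @return Covariate tibble with identifiers, demographics, the four (not yet
#'   masked) measurements, binary flags, `ethnicity_white`, `true_lp` and
#'   `true_risk` (the model evaluated on the generated covariates).
#' @export
generate_covariates <- function(n, config = af_cohort_config(),
                                seed = 20140101) {
  stopifnot(inherits(config, "af_cohort_config"), n > 0)
  flags <- names(config$prevalence)
  cf <- count_flags()

  set.seed(seed)
  u_sex <- stats::runif(n)
  z_hw <- matrix(stats::rnorm(2 * n), ncol = 2)
  z_bp <- matrix(stats::rnorm(2 * n), ncol = 2)
  u_age <- stats::runif(n)
  u_flags <- matrix(stats::runif(n * length(flags)), ncol = length(flags),
                    dimnames = list(NULL, flags))
  u_prac <- stats::runif(n)
  u_miss <- withr_seed(seed + 1, stats::runif(n))

  female <- u_sex < config$female_frac

  # --- fixed point: age location, flag intercepts, missingness intercepts ---
  mu <- config$age_mean
  a <- logit(config$prevalence)
  c0 <- logit(config$complete_frac) -
    config$miss_count_slope * 2.5
  c_sex <- 0
  # achievable accuracy is bounded by the flip granularity of the complete
  # subset, so tolerances widen for small samples
  m_exp <- max(30, config$complete_frac * n)
  tol_age <- max(0.02, 60 / m_exp)
  tol_logit <- max(0.02, 60 / m_exp)
  converged <- FALSE
  for (it in seq_len(60L)) {
    age <- floor(qtruncnorm_lower(u_age, mu, config$age_sd, config$age_min))
    pf <- vapply(flags, function(f) {
      invlogit(a[[f]] + config$age_slopes[[f]] * (age - 65))
    }, numeric(n))
    fl <- u_flags < pf
    cnt <- rowSums(fl[, cf, drop = FALSE])
    pc <- invlogit(c0 + config$miss_count_slope * cnt +
                     config$miss_age_slope * (age - 65) +
                     c_sex * as.numeric(female))
    complete <- u_miss < pc
    # with very small complete subsets, calibrate on the whole sample
    cal <- if (sum(complete) >= 30L) complete else rep(TRUE, n)
    m_c <- sum(cal)

    err_frac <- logit(config$complete_frac) - slogit(mean(complete), n)
    err_age <- config$age_mean - mean(age[cal])
    err_sex <- logit(config$female_frac) - slogit(mean(female[cal]), m_c)
    err_a <- vapply(flags, function(f) {
      logit(config$prevalence[[f]]) - slogit(mean(fl[cal, f]), m_c)
    }, numeric(1))

    if (abs(err_age) < tol_age && abs(err_frac) < tol_logit &&
        abs(err_sex) < tol_logit && max(abs(err_a)) < tol_logit) {
      converged <- TRUE
      break
    }
    # damp later steps: full Newton-like steps can overshoot into a limit
    # cycle when a block of patients flips together
    s <- if (it <= 10L) 1 else if (it <= 35L) 0.5 else 0.25
    c0 <- c0 + s * err_frac
    mu <- mu + s * err_age
    c_sex <- c_sex + s * err_sex
    a <- a + s * err_a
  }
  if (!converged) {
    worst <- flags[which.max(abs(err_a))]
    stop(sprintf(
      "covariate calibration did not converge (worst covariate: %s)", worst),
      call. = FALSE)
  }

  # sex-offset bivariate normals; within-sex SD chosen so the overall
  # marginal SD matches the configured one
  within_sd <- function(sd_total, diff) {
    between <- config$female_frac * (1 - config$female_frac) * diff^2
    if (sd_total^2 <= between) {
      stop("sex offset too large for the configured marginal SD", call. = FALSE)
    }
    sqrt(sd_total^2 - between)
  }
  h_mu <- config$height_mean +
    ifelse(female, -(1 - config$female_frac), config$female_frac) *
    config$sex_height_diff
  w_mu <- config$weight_mean +
    ifelse(female, -(1 - config$female_frac), config$female_frac) *
    config$sex_weight_diff
  h_sd <- within_sd(config$height_sd, config$sex_height_diff)
  w_sd <- within_sd(config$weight_sd, config$sex_weight_diff)
  r <- config$height_weight_cor
  height <- h_mu + h_sd * z_hw[, 1]
  weight <- w_mu + w_sd * (r * z_hw[, 1] + sqrt(1 - r^2) * z_hw[, 2])
  r2 <- config$sbp_dbp_cor
  sbp <- config$sbp_mean + config$sbp_sd * z_bp[, 1]
  dbp <- config$dbp_mean +
    config$dbp_sd * (r2 * z_bp[, 1] + sqrt(1 - r2^2) * z_bp[, 2])

  out <- tibble::tibble(
    patient_id = sprintf("p%07d", seq_len(n)),
    practice_id = sprintf("pr%03d", 1L + floor(u_prac * config$n_practices)),
    sex = ifelse(female, "female", "male"),
    age = as.numeric(age),
    height = height, weight = weight, sbp = sbp, dbp = dbp,
    smoking = fl[, "smoking"],
    antihypertensive = fl[, "antihypertensive"],
    hypertension = fl[, "hypertension"],
    diabetes = fl[, "diabetes"],
    heart_failure = fl[, "heart_failure"],
    myocardial_infarction = fl[, "myocardial_infarction"],
    stroke = fl[, "stroke"],
    tia = fl[, "tia"],
    atherosclerosis = fl[, "atherosclerosis"],
    angina = fl[, "angina"],
    ethnicity_white = TRUE)
  out$true_lp <- charge_af_lp(out, config$model)
  out$true_risk <- charge_af_risk(out$true_lp, config$model)
  attr(out, "solved") <- list(
    age_mu_pop = mu, flag_intercepts = a,
    miss_intercept = c0, miss_sex_offset = c_sex, iterations = it)
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  out
}

#' Impose informative measurement missingness
#'
#' The probability that all four measurements are recorded follows a
#' logit-linear model in comorbidity count and age (plus a small solved sex
#' offset), so completeness is missing-not-at-random: complete cases are more
#' comorbid and older than incomplete ones. Incomplete patients have a
#' uniformly chosen non-empty subset of the four measurements masked. The
#' four original columns are preserved as `*_full` (so the generating truth
#' stays available for incomplete cases) and the working columns get `NA`
#' where masked.
#'
#' @param table Covariate tibble from [generate_covariates()].
#' @param config An [af_cohort_config()].
#' @param seed Seed; when `table` carries solved intercepts from the joint
#'   calibration, pass the same `seed + 1` used there so the completeness
#'   draw coincides with the calibrated one.
#' @return The table with `*_full` columns, masked measurement columns and a
#'   logical `complete`.
#' @export
impose_missingness <- function(table, config = af_cohort_config(),
                               seed = 20140102) {
  n <- nrow(table)
  cnt <- rowSums(as.matrix(table[, count_flags()]))
  set.seed(seed)
  u_miss <- stats::runif(n)
  pattern <- 1L + floor(stats::runif(n) * 15) # non-empty subset of 4 (bitmask)

  solved <- attr(table, "solved")
  c_sex <- solved$miss_sex_offset %||% 0
  female <- as.numeric(table$sex == "female")
  lin <- config$miss_count_slope * cnt +
    config$miss_age_slope * (table$age - 65) + c_sex * female
  c0 <- solved$miss_intercept %||% stats::uniroot(
    function(b) mean(invlogit(b + lin)) - config$complete_frac,
    c(-30, 30), tol = 1e-10)$root
  complete <- u_miss < invlogit(c0 + lin)

  out <- table
  meas <- c(height = 1L, weight = 2L, sbp = 4L, dbp = 8L)
  for (nm in names(meas)) {
    out[[paste0(nm, "_full")]] <- out[[nm]]
    masked <- !complete & bitwAnd(pattern, meas[[nm]]) > 0L
    out[[nm]][masked] <- NA_real_
  }
  out$complete <- complete
  attr(out, "solved") <- solved
  attr(out, "config") <- attr(table, "config") %||% config
  attr(out, "seed") <- attr(table, "seed")
  out
}

# generating linear predictor after optional miscalibration distortion
generating_risk <- function(table, config) {
  lp <- table$true_lp
  if (is.null(lp)) {
    full <- table
    for (nm in c("height", "weight", "sbp", "dbp")) {
      fc <- paste0(nm, "_full")
      if (fc %in% names(full)) full[[nm]] <- full[[fc]]
    }
    lp <- charge_af_lp(full, config$model)
  }
  cc <- config$model$centering_constant
  charge_af_risk(cc + config$lp_slope * (lp - cc) + config$lp_shift,
                 config$model)
}

#' Simulate latent AF event times
#'
#' Each patient gets a constant hazard matched to their generating 5-year
#' risk on the hazard scale: \eqn{\lambda_i = -m \ln(1 - p_i)/H}, so the
#' event probability within the horizon is \eqn{1 - (1 - p_i)^m}. Because
#' \eqn{-\ln(1 - p_i) \propto \exp(lp_i)} under the baseline-survival power
#' form, the generator is an exact proportional-hazards model in the linear
#' predictor for any multiplier, and a Cox refit of the generating linear
#' predictor recovers slope 1 by construction. The multiplier `m` is solved
#' so the realised within-horizon event fraction among complete cases equals
#' the configured target (the constant-hazard shape is exchangeable with any
#' shape matching the same 5-year survival). Event times are exponential.
#'
#' @param table Cohort tibble (after [impose_missingness()]; without a
#'   `complete` column the target applies to all rows).
#' @param config An [af_cohort_config()].
#' @param seed Seed for the exponential draws.
#' @return The table with `event_risk5y` (the generating horizon risk
#'   \eqn{1-(1-p_i)^m}) and the latent `af_time`; the multiplier is in
#'   `attr(, "hazard_multiplier")`.
#' @export
simulate_events <- function(table, config = af_cohort_config(),
                            seed = 20140103) {
  n <- nrow(table)
  p_raw <- generating_risk(table, config)
  set.seed(seed)
  u_t <- stats::runif(n)
  sub <- if ("complete" %in% names(table)) table$complete else rep(TRUE, n)
  t_of <- function(m) {
    config$horizon * log(u_t) / (m * log1p(-p_raw))
  }
  m <- config$hazard_multiplier
  if (is.null(m)) {
    fr <- function(m) mean(t_of(m)[sub] <= config$horizon) -
      config$target_cum_incidence
    if (fr(1e3) < 0) {
      stop("target cumulative incidence unattainable (hazard multiplier at bound)",
           call. = FALSE)
    }
    m <- stats::uniroot(fr, c(1e-6, 1e3), tol = 1e-8)$root
  }
  out <- table
  out$event_risk5y <- 1 - (1 - p_raw)^m
  out$af_time <- t_of(m)
  attr(out, "solved") <- attr(table, "solved")
  attr(out, "config") <- attr(table, "config") %||% config
  attr(out, "seed") <- attr(table, "seed")
  attr(out, "hazard_multiplier") <- m
  out
}

# loss times (years) from geometric per-quarter dropout; quarter 1 is always
# registered, so the earliest possible loss is at 0.25 y. Inf = never lost.
loss_times_from_u <- function(u, q, n_quarters) {
  if (q <= 0) return(rep(Inf, length(u)))
  g <- floor(log(u) / log1p(-q))
  lt <- 0.25 * (1 + g)
  lt[lt >= 0.25 * n_quarters] <- Inf
  lt
}

#' Simulate quarterly-registration censoring and resolve outcomes
#'
#' Individual dropout is geometric per quarter (optionally combined with
#' practice-level dropout blocks, which cluster loss dates within practices);
#' the per-quarter probability is solved so the realised mean observed
#' follow-up among complete cases equals the configured target. Outcomes are
#' resolved as the earliest of AF event, loss to follow-up and the horizon.
#'
#' @param table Cohort tibble with `af_time` (from [simulate_events()]).
#' @param config An [af_cohort_config()].
#' @param seed Seed for the dropout draws.
#' @return The table with `time_years`, `event`, `censor_reason` and
#'   `loss_quarter` (index of the first absent follow-up quarter, `NA` when
#'   never lost); the solved probability is in `attr(, "dropout_quarterly")`.
#' @export
simulate_censoring <- function(table, config = af_cohort_config(),
                               seed = 20140104) {
  n <- nrow(table)
  stop_missing_cols(table, "af_time", "cohort")
  set.seed(seed)
  u_drop <- stats::runif(n)
  prac_loss <- rep(Inf, n)
  if (config$practice_dropout_quarterly > 0) {
    pr <- sort(unique(table$practice_id))
    u_pr <- stats::runif(length(pr))
    pl <- loss_times_from_u(u_pr, config$practice_dropout_quarterly,
                            config$n_quarters)
    prac_loss <- pl[match(table$practice_id, pr)]
  }
  sub <- if ("complete" %in% names(table)) table$complete else rep(TRUE, n)
  t_ev <- table$af_time
  obs_time <- function(q) {
    pmin(t_ev, pmin(loss_times_from_u(u_drop, q, config$n_quarters), prac_loss),
         config$horizon)
  }
  q <- config$dropout_quarterly
  if (is.null(q)) {
    f <- function(q) mean(obs_time(q)[sub]) - config$target_mean_followup
    if (f(0) < 0) {
      stop("target mean follow-up unattainable: event times alone fall below it",
           call. = FALSE)
    }
    q <- stats::uniroot(f, c(0, 0.9), tol = 1e-9)$root
  }
  loss <- pmin(loss_times_from_u(u_drop, q, config$n_quarters), prac_loss)
  tm <- pmin(t_ev, loss, config$horizon)
  event <- t_ev <= pmin(loss, config$horizon)
  out <- table
  out$time_years <- tm
  out$event <- event
  out$censor_reason <- dplyr::case_when(
    event ~ "af_event",
    loss <= config$horizon ~ "lost_to_followup",
    TRUE ~ "admin_end")
  lq <- rep(NA_integer_, n)
  fin <- is.finite(loss)
  lq[fin] <- as.integer(round(loss[fin] / 0.25)) + 1L
  out$loss_quarter <- lq
  attr(out, "solved") <- attr(table, "solved")
  attr(out, "config") <- attr(table, "config") %||% config
  attr(out, "seed") <- attr(table, "seed")
  attr(out, "hazard_multiplier") <- attr(table, "hazard_multiplier")
  attr(out, "dropout_quarterly") <- q
  out
}

#' Generate a complete synthetic cohort
#'
#' Composes covariate generation, informative missingness, event simulation
#' and registration censoring. The hazard multiplier and the dropout
#' probability are solved *jointly* on the realised draws (alternating 1-D
#' root finds) so that among complete cases the Kaplan-Meier 5-year
#' cumulative incidence and the mean observed follow-up both meet their
#' configured targets under censoring. Fully deterministic given
#' `(config, seed)`; the seeds of the four stages are `seed .. seed + 3` and
#' a provenance hash of `(config, n, seed)` is attached.
#'
#' @param n Number of patients.
#' @param config An [af_cohort_config()].
#' @param seed Integer seed.
#' @return Cohort tibble with covariates, `*_full` columns, `complete`,
#'   `true_lp`, `true_risk`, `event_risk5y`, `af_time`, `time_years`,
#'   `event`, `censor_reason`, `loss_quarter`. Attributes: `config`, `seed`,
#'   `provenance`, `hazard_multiplier`, `dropout_quarterly`, `solved`.
#' @examples
#' coh <- generate_cohort(500, seed = 1)
#' mean(coh$complete)
#' @export
generate_cohort <- function(n, config = af_cohort_config(), seed = 20140101) {
  cov <- generate_covariates(n, config, seed = seed)
  tab <- impose_missingness(cov, config, seed = seed + 1)

  p_raw <- generating_risk(tab, config)
  u_t <- withr_seed(seed + 2, stats::runif(n))
  u_drop <- withr_seed(seed + 3, stats::runif(n))
  prac_loss <- rep(Inf, n)
  if (config$practice_dropout_quarterly > 0) {
    pr <- sort(unique(tab$practice_id))
    u_pr <- withr_seed(seed + 3, {
      stats::runif(n) # keep the individual stream identical
      stats::runif(length(pr))
    })
    prac_loss <- loss_times_from_u(u_pr, config$practice_dropout_quarterly,
                                   config$n_quarters)[match(tab$practice_id, pr)]
  }
  sub <- tab$complete
  t_of <- function(m) config$horizon * log(u_t) / (m * log1p(-p_raw))
  loss_of <- function(q) {
    pmin(loss_times_from_u(u_drop, q, config$n_quarters), prac_loss)
  }
  km_inc <- function(tt, loss) {
    tm <- pmin(tt, loss, config$horizon)[sub]
    ev <- (tt <= pmin(loss, config$horizon))[sub]
    km_failure_at(kaplan_meier(tm, as.integer(ev)), config$horizon)$failure
  }

  m <- config$hazard_multiplier
  q <- config$dropout_quarterly
  if (is.null(m) || is.null(q)) {
    m_cur <- m %||% stats::uniroot(
      function(mm) mean(t_of(mm)[sub] <= config$horizon) -
        config$target_cum_incidence,
      c(1e-6, 1e3), tol = 1e-8)$root
    q_cur <- q %||% 0
    for (round in 1:4) {
      if (is.null(q)) {
        tt <- t_of(m_cur)
        f <- function(qq) mean(pmin(tt, loss_of(qq), config$horizon)[sub]) -
          config$target_mean_followup
        if (f(0) < 0) stop("target mean follow-up unattainable", call. = FALSE)
        q_cur <- stats::uniroot(f, c(0, 0.9), tol = 1e-9)$root
      }
      if (is.null(m)) {
        loss <- loss_of(q_cur)
        g <- function(mm) km_inc(t_of(mm), loss) - config$target_cum_incidence
        m_cur <- stats::uniroot(g, c(1e-6, 1e3), tol = 1e-8)$root
      }
    }
    m <- m_cur; q <- q_cur
  }

  cfg_fixed <- config
  cfg_fixed$hazard_multiplier <- m
  cfg_fixed$dropout_quarterly <- q
  out <- simulate_events(tab, cfg_fixed, seed = seed + 2)
  out <- simulate_censoring(out, cfg_fixed, seed = seed + 3)
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  attr(out, "provenance") <- list(
    config_hash = rlang::hash(unclass(config)),
    n = n, seed = seed,
    hash = rlang::hash(list(unclass(config), n, seed)))
  out
}

#' Re-express a synthetic cohort as raw EHR-like records
#'
#' Emits dated measurement entries within the baseline year (the
#' closest-to-baseline entry carries the cohort value, at full precision;
#' about half the patients also get an earlier decoy entry), morbidity flags
#' as coded episodes starting before baseline, antihypertensive use as an
#' ATC-coded prescription in the baseline year, a smoking-status entry for
#' everyone, incident AF as a post-baseline episode, and the quarterly
#' registration grid (absent from the loss quarter onward for patients
#' censored by loss to follow-up). Round-tripping through
#' [extract_baseline()], [split_complete_cases()] and [derive_followup()]
#' reproduces the flat cohort: covariates, flags and completeness exactly
#' (age as completed years), times up to the calendar-quarter versus
#' 365.25-day-year conversion (< 0.01 y).
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param config The generator config (for the horizon/quarter grid).
#' @param seed Seed for episode dates and decoys.
#' @param baseline_date Baseline date.
#' @param map A [code_map()] supplying the emitted codes.
#' @return An [ehr_records()] object.
#' @export
emit_raw_records <- function(cohort, config = af_cohort_config(),
                             seed = 20140105,
                             baseline_date = as.Date("2014-01-01"),
                             map = code_map()) {
  n <- nrow(cohort)
  baseline_date <- as.Date(baseline_date)
  set.seed(seed)

  yr <- 2014L - as.integer(cohort$age)
  birth <- as.Date(sprintf("%04d-01-01", yr)) -
    sample.int(364L, n, replace = TRUE) + 1L # offset 0..363 keeps completed years
  patients <- tibble::tibble(
    patient_id = cohort$patient_id, practice_id = cohort$practice_id,
    birth_date = birth, sex = cohort$sex)

  kinds <- c(height = "height_cm", weight = "weight_kg",
             sbp = "sbp_mmHg", dbp = "dbp_mmHg")
  meas_list <- list()
  for (nm in names(kinds)) {
    present <- !is.na(cohort[[nm]])
    if (!any(present)) next
    prim_date <- baseline_date - sample.int(150L, n, replace = TRUE)
    meas_list[[nm]] <- tibble::tibble(
      patient_id = cohort$patient_id[present],
      kind = kinds[[nm]],
      value = sprintf("%.17g", cohort[[nm]][present]),
      date = prim_date[present])
    decoy <- present & stats::runif(n) < 0.5
    if (any(decoy)) {
      meas_list[[paste0(nm, "_decoy")]] <- tibble::tibble(
        patient_id = cohort$patient_id[decoy],
        kind = kinds[[nm]],
        value = sprintf("%.17g", cohort[[nm]][decoy] *
                          stats::runif(sum(decoy), 0.95, 1.05)),
        date = prim_date[decoy] - sample.int(180L, sum(decoy), replace = TRUE))
    }
  }
  meas_list$smoking <- tibble::tibble(
    patient_id = cohort$patient_id,
    kind = "smoking_status",
    value = ifelse(cohort$smoking, "current", "never"),
    date = baseline_date - sample.int(150L, n, replace = TRUE))
  measurements <- dplyr::bind_rows(meas_list)

  flag_conds <- c(heart_failure = "heart_failure",
                  myocardial_infarction = "myocardial_infarction",
                  hypertension = "hypertension", diabetes = "diabetes",
                  stroke = "stroke", tia = "tia",
                  atherosclerosis = "atherosclerosis", angina = "angina")
  epi_list <- list()
  for (nm in names(flag_conds)) {
    has <- cohort[[nm]]
    if (!any(has)) next
    codes <- map$conditions[[flag_conds[[nm]]]]
    epi_list[[nm]] <- tibble::tibble(
      patient_id = cohort$patient_id[has],
      code = codes[1L + (seq_len(sum(has)) %% length(codes))],
      start_date = baseline_date - sample.int(360L, sum(has), replace = TRUE))
  }
  is_event <- as.logical(cohort$event)
  if (any(is_event)) {
    af_date <- baseline_date + round(cohort$time_years[is_event] * 365.25)
    window_end <- as.Date("2018-12-31")
    epi_list$af <- tibble::tibble(
      patient_id = cohort$patient_id[is_event],
      code = map$conditions$atrial_fibrillation[1],
      start_date = pmin(af_date, window_end))
  }
  episodes <- dplyr::bind_rows(epi_list)

  aht <- cohort$antihypertensive
  prescriptions <- tibble::tibble(
    patient_id = cohort$patient_id[aht],
    atc_code = paste0(map$medications$antihypertensive[1], "A"),
    date = baseline_date - sample.int(360L, sum(aht), replace = TRUE))

  q_starts <- seq(as.Date("2013-01-01"), by = "quarter",
                  length.out = 4L + config$n_quarters)
  lost <- cohort$censor_reason == "lost_to_followup"
  # follow-up quarter j (1-based) present unless the patient was lost at or
  # before it; baseline-year quarters always present
  reg <- tidyr::expand_grid(patient_id = cohort$patient_id,
                            quarter_start = q_starts)
  fu_index <- rep(seq_along(q_starts) - 4L, times = n) # <= 0 during 2013
  loss_q <- rep(ifelse(lost, cohort$loss_quarter, NA_integer_),
                each = length(q_starts))
  reg$present <- fu_index < 1L | is.na(loss_q) | fu_index < loss_q
  ehr_records(patients, episodes, measurements, prescriptions, reg,
              window_start = as.Date("2013-01-01"),
              window_end = as.Date("2018-12-31"))
}
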