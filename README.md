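# chargeaf

External validation of the **CHARGE-AF** 5-year atrial fibrillation (AF) risk
model in routine-care (EHR-style) cohorts, and evaluation of its use as a
triage test for AF screening.

AF screening programmes need to decide *whom* to screen. CHARGE-AF predicts an
individual's 5-year risk of new AF from eleven covariates that primary-care
records largely already contain:

```
p = 1 - S0 ^ exp(ΣbX - c),   S0 = 0.9718412736,  c = 12.5815600
ΣbX = 0.5083·age/5 + 0.46491·white + 0.2478·height/10 + 0.1155·weight/15
    + 0.1972·SBP/20 - 0.1013·DBP/10 + 0.35931·smoking + 0.34889·antihypertensive
    + 0.23666·diabetes + 0.70127·heart failure + 0.49659·MI
```

This package is aimed at researchers validating prognostic models on
registry data. It provides, as tidyverse-style functions over data frames:

* **Cohort derivation** — `extract_baseline()`, `apply_eligibility()`,
  `split_complete_cases()`, `compare_groups()`: from raw coded records
  (episodes / measurements / prescriptions / quarterly registration CSVs) to
  an analysis cohort, with closest-to-baseline measurement selection and a
  cohort-flow table. Diagnosis/medication code lists are configurable via
  `code_map()`.
* **Risk scores** — `charge_af_lp()`, `charge_af_risk()`, `cha2ds2_vasc()`,
  `categorize_risk()`, `score_cohort()`, `contribution_decomposition()`.
* **Censored outcomes** — the quarterly loss-to-follow-up rule
  (`loss_to_followup_date()`), outcome resolution (`resolve_outcome()`,
  `derive_followup()`), Kaplan-Meier with Greenwood variance
  (`kaplan_meier()`), incidence rates.
* **Validation statistics** — Harrell's C with bootstrap CI (`harrell_c()`),
  calibration tables and a censoring-aware Nam-D'Agostino-style
  goodness-of-fit test (`calibration_table()`, `nam_dagostino()`),
  calibration slope (`cox_fit_single()`), categorical NRI under censoring
  (`categorical_nri()`), risk-stratified KM (`stratified_km()`), stratified
  reports (`stratified_validation()`), and `validate_charge_af()` tying it
  together. `tidy()`/`glance()` methods and `autoplot()` figures included.
* **Screening triage** — `triage_table()` and `sensitivity_curve()` for
  risk cut-offs (default 2.5%, 5%, 10%).
* **Synthetic EHR cohorts** — `generate_cohort()` plus staged operations and
  `emit_raw_records()`: a generator calibrated so its *complete-case* subset
  matches the published validation population (mean age 65.5, 52.5% female,
  published comorbidity prevalences, 17.2% complete cases under informative
  missingness, 4.7% 5-year KM incidence, 3.5 y mean follow-up). Real
  licensed data are never required.

See `vignettes/methods.Rmd` for the statistical design and its rationale.

## Worked example

```r
library(chargeaf)

coh <- generate_cohort(50000, seed = 2014)          # synthetic EHR cohort
cc  <- split_complete_cases(coh)$complete |> score_cohort()
rep <- validate_charge_af(cc, B = 200, seed = 2014, stratified = FALSE)
rep
#> CHARGE-AF validation: n = 8566, events = 297 (4.7% cumulative, 9.9/1000 PY)
#>   C-statistic: 0.820 [0.802, 0.847]
#>   Calibration slope: 0.99 [0.90, 1.08]
#>   Goodness of fit: chi2 = 250.0 (df 10, p = 5.31e-48)
#>   NRI vs age: -0.043 | NRI vs CHA2DS2-VASc: 0.046

rep$triage[, c("cutoff", "pct_high", "sensitivity", "cum_incidence_high")]
#>   cutoff pct_high sensitivity cum_incidence_high
#> 1  0.025     63.8       0.953             0.0697
#> 2  0.05      43.3       0.859             0.0920
#> 3  0.1       23.7       0.687             0.132
```

Reading the numbers: the complete-case subset has the calibrated 4.7%
cumulative 5-year AF incidence. Discrimination is high (C = 0.82) because the
synthetic events are generated from the model itself. The calibration *slope*
is 1 (the risk ordering is correct), but the goodness-of-fit test rejects
loudly: the cohort's observed incidence is well below the model's mean
predicted risk, so unmodified CHARGE-AF *overestimates absolute risk* in this
population — exactly the failure mode a level-calibration test should flag,
and the reason the generator's hazard multiplier is solved rather than fixed
at 1. The triage table shows the screening trade-off: lowering the cut-off
from 10% to 2.5% raises sensitivity from 0.69 to 0.95 while expanding the
screened fraction from 24% to 64% and diluting the AF yield per screened
patient (13.2% down to 7.0%).

Plots: `autoplot(rep$calibration)`, `autoplot(rep$km_strata)`,
`plot_sensitivity_curve(sensitivity_curve(cc))`.

A thin command-line wrapper lives at `inst/cli/chargeaf-cli.R`
(`simulate` / `validate` / `triage` subcommands, CSV in/out).

## Raw-record input schema

`read_ehr_records(dir)` expects five CSVs keyed by `patient_id`:
`patients.csv` (`practice_id`, `birth_date`, `sex`), `episodes.csv`
(`code`, `start_date`), `measurements.csv` (`kind` in `height_cm`,
`weight_kg`, `sbp_mmHg`, `dbp_mmHg`, `smoking_status`; `value`; `date`),
`prescriptions.csv` (`atc_code`, `date`), `registration.csv`
(`quarter_start`, `present`). Alternatively, supply a flat cohort CSV with
one row per patient (columns as in `score_cohort()` input plus `time_years`,
`event`) to `run_validate()` directly.

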