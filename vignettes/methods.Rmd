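---
title: "Methods: validating the CHARGE-AF risk model in routine-care cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating the CHARGE-AF risk model in routine-care cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chargeaf)
```

## The problem

Atrial fibrillation (AF) is a common, frequently silent arrhythmia whose main
preventable harm — ischaemic stroke — can be averted by anticoagulation. That
makes AF screening attractive, and makes *patient selection for screening* the
central design question: screening everyone over 40 is wasteful, and selecting
on age alone is crude. Multivariable risk models are the alternative, and the
CHARGE-AF equation is the leading candidate: an eleven-covariate Cox-type model
of 5-year AF risk using variables that routine primary-care electronic health
records (EHRs) mostly already contain.

`chargeaf` implements the complete analysis pipeline for externally validating
CHARGE-AF on an EHR-style cohort and for evaluating it as a screening triage
test: cohort derivation from raw coded records, risk scoring, censoring-aware
validation statistics, and cut-off triage tables. Because realistic
primary-care databases are license-restricted, the package ships a calibrated
synthetic cohort generator so that every step — including the tests — runs on
data with known ground truth.

## The risk model

CHARGE-AF predicts the 5-year probability of new AF as

$$p = 1 - S_0^{\exp(\Sigma bX - c)},$$

with baseline AF-free survival $S_0 = 0.9718412736$, centering constant
$c = 12.5815600$, and linear predictor

$$\Sigma bX = 0.5083\,\tfrac{\text{age}}{5} + 0.46491\,\text{white} +
0.2478\,\tfrac{\text{height}}{10} + 0.1155\,\tfrac{\text{weight}}{15} +
0.1972\,\tfrac{\text{SBP}}{20} - 0.1013\,\tfrac{\text{DBP}}{10} +
0.35931\,\text{smoking} + 0.34889\,\text{antihypertensive} +
0.23666\,\text{diabetes} + 0.70127\,\text{HF} + 0.49659\,\text{MI}$$

(age in years, height cm, weight kg, blood pressures mm Hg, binaries 0/1).
Two modelling conventions matter:

* **Ethnicity** is carried as a constant white/Caucasian indicator by default.
  Dutch primary-care records may not store ethnicity, and dropping the term
  instead would systematically underestimate absolute risk, which is fatal for
  absolute-risk triage. The flag is a per-patient column, so mixed cohorts can
  set it.
* **Completeness.** The model is only defined when all four body measurements
  are present. `charge_af_lp()` raises an error on missing values rather than
  zero-filling; `score_cohort()` returns `NA` for incomplete cases. No
  imputation is offered anywhere — measurement missingness in routine care is
  informative (see below), and imputation would quietly change the estimand.

Risk categories use cut points 2.5% and 5%. The printed category "2.5%–5%" is
closed on both ends while its neighbours are strict, so a risk exactly at
either cut point is *intermediate*; the same convention generalises to longer
threshold lists (first boundary moves up, later boundaries stay down). Triage
dichotomisation (`triage_table()`) instead uses `risk >= cutoff`, so a patient
exactly at the screening cut-off is screened.

The CHA2DS2-VASc comparator is the usual 0–9 integer: heart failure,
hypertension, diabetes, vascular disease and female sex score 1; stroke/TIA
scores 2; age 65–74 scores 1 and 75+ scores 2. Its "vascular disease"
component is not operationalised identically across databases; here it
defaults to MI, atherosclerotic arterial disease or angina, and both the flag
set and the diagnosis-code mapping (`code_map()`) are configurable. The
shipped code map uses broad ICPC-1-style chapter codes and ATC C02/C03/C07/
C08/C09 prefixes; real-data users must substitute the operational lists of
their registry.

## Cohort derivation from raw records

`extract_baseline()` reproduces the EHR conventions of a registry with a
Jan-1 baseline and a one-calendar-year measurement window:

* measurement entries within `[baseline - 365 d, baseline)` are eligible and
  the entry *closest to baseline* is used; entries of the same kind on the
  same date tie-break to the lexicographically smaller value (deterministic,
  order-invariant — the source registries do not document a rule);
* morbidity is "any episode starting before baseline" (an optional
  per-condition lookback window exists because registries may deactivate
  non-chronic episodes such as AF and MI after a contact-free year; the
  one-year baseline window effectively extends that lookback by a year);
* antihypertensive use requires a prescription *within the baseline year*,
  not merely any historical prescription (recency is the point of the
  baseline window; this resolves an ambiguity the source conventions leave
  open);
* age is completed years at baseline.

Eligibility (`apply_eligibility()`) keeps patients aged 40+, AF-free before
baseline, registered in all four baseline-year quarters, at practices with any
post-baseline data, and records the attrition flow. The final set is
independent of filter order; only the flow decomposition depends on it.

## Follow-up and censoring

Registration is quarterly. Loss to follow-up is the first day of the earliest
absent run of at least four consecutive quarters, or of any trailing absent
run that includes the final quarter. Follow-up ends at the earliest of AF
diagnosis, loss, and the 5-year horizon; an AF code dated after the loss date
is unobservable in this design and the patient counts as censored at loss.
Death is not distinguishable from other loss in such registries, so there is
no competing-risk treatment — estimates are cause-specific. Years are fixed at
365.25 days. At tied times events precede censorings in the risk set (the
standard product-limit convention). Kaplan–Meier estimation is delegated to
`survival::survfit()`, with Greenwood's variance computed explicitly
($S^2\sum d_i/(n_i(n_i-d_i))$, set to 0 where $S=0$).

## Validation statistics

**Discrimination.** Harrell's C over usable pairs: the shorter observed time
must be an event; an event tied in time with a censoring is usable (the
censored patient survived at least as long); marker ties count 1/2; two events
at the same time are not comparable. The implementation runs in $O(nd)$ and is
tested for exact equality against an $O(n^2)$ enumeration oracle on fixtures
up to $n = 30$, and against `survival::concordance()` on untied data. The CI
is a seeded patient-level percentile bootstrap (default $B = 200$), the same
machinery used for the NRI, since no analytic CI convention is implied by the
reporting style being mirrored.

**Calibration slope.** The coefficient of the model's linear predictor in a
single-covariate Cox refit (Efron ties, Newton–Raphson to $10^{-9}$, max 50
iterations, via `survival::coxph`); 1 is ideal, below 1 indicates overfitting
relative to the validation population. Non-convergence and monotone
likelihoods raise errors rather than returning junk.

**Calibration table and goodness of fit.** Patients are ranked by predicted
risk (ties broken by a stable id so groups are reproducible) and split into
near-equal deciles; each group contributes its mean predicted risk and the KM
failure at the horizon with a Greenwood CI. The Nam–D'Agostino-style
chi-squared compares the two across groups. Two design points deserve
emphasis, both decided after measuring the alternatives on simulated nulls
(the acceptance suite recomputes these checks):

* *Variance.* The classical binomial denominator $\bar p_g(1-\bar p_g)/n_g$
  understates the sampling variance of a censored KM estimate, and measured
  rejection of a true null ran at 23–34% instead of 5%. The default therefore
  standardises by the Greenwood variance of each group's KM estimate; the
  binomial form remains available (`variance = "binomial"`).
* *Degrees of freedom.* In external validation nothing is estimated from the
  grouped data, so all $G$ standardised deviations contribute and the default
  reference is $\chi^2_G$; `df = "G-1"` gives the internal-validation
  convention.

The statistic's asymptotics need adequate events per group: with roughly
thirty or more events per decile the measured type-I error at $n = 5000$ over
500 seeded replicates is 0.056. Groups with one or two events (which the
heavily right-skewed CHARGE-AF risk profile produces in its bottom deciles)
inflate any variant of the statistic; `calibration_table(min_events = )`
therefore supports the standard remedy of merging adjacent sparse groups, and
the goodness-of-fit test should be read in that regime.

**NRI.** Categorical net reclassification improvement at the 2.5%/5% cut
points, censoring-aware: within the upward- and downward-reclassified groups
the event proportion at the horizon is estimated by KM, giving
$NRI_{ev} = [n_{up}F_{up} - n_{down}F_{down}]/(nF)$ and its non-event
counterpart; the overall NRI is their sum by construction, and without
censoring the formulas collapse to the closed-form contingency-table NRI
(tested against enumeration). Comparator predictors (age; CHA2DS2-VASc) are
not probabilities, so they are mapped to absolute horizon risks by a
single-covariate Cox fit plus the Breslow baseline cumulative hazard
(`marker_to_risk()`) before categorisation — the mapping the original
reporting leaves unstated, made explicit and testable here.

**Stratified analyses** re-run C / slope / goodness-of-fit within age 65+,
age < 65, men, women, CHA2DS2-VASc $\geq 2$ and $< 2$; strata under 50
patients (configurable) are skipped with a warning.

## The synthetic cohort generator

`generate_cohort()` emulates the *validation population* of a nationwide
Dutch primary-care study of patients aged 40+ and AF-free at baseline. The
defining feature of that population is that its published baseline table
describes the **complete-case subset** — the 17.2% of patients with all four
measurements recorded — and that completeness is informative: complete cases
are older, more comorbid and at higher AF risk. The generator therefore
treats every published figure as a complete-case calibration target and
solves population-level parameters to hit it:

| target (complete cases) | default | solved parameter |
|---|---|---|
| mean age (years) | 65.5 (SD 11.4, floor 40) | population age location |
| female share | 52.5% | sex-specific recording offset |
| comorbidity prevalences | per published table (e.g. antihypertensives 70.9%, diabetes 42.7%, heart failure 4.2%) | per-condition logistic intercepts |
| complete-case fraction | 17.2% | missingness intercept |
| KM 5-year cumulative AF incidence | 4.7% | hazard multiplier $m$ |
| mean observed follow-up (years) | 3.5 | per-quarter dropout probability |

The first four are solved jointly by a damped fixed-point iteration under
common random numbers (deterministic given the seed; tolerance 0.02 on the
age mean and on logits at large $n$, widening with the flip granularity of
small samples; convergence failure is an error naming the worst covariate).
The last two are 1-D root finds on the *realised* draws, alternated so both
targets hold simultaneously under censoring; raising any target raises its
solved parameter (tested). Because the targets are complete-case statistics,
the generated *population* is younger and less comorbid than its complete
cases, which reproduces the published complete-versus-incomplete contrast
rather than contradicting it.

Remaining structure: age is truncated-normal and reported in completed years;
height/weight are bivariate normal within sex (male–female offsets 13 cm /
12 kg, within-sex correlation 0.5) with overall marginals 170.0 (9.9) cm and
82.5 (16.8) kg; SBP/DBP are bivariate normal (137.3 (16.3) / 80.5 (10.5)
mm Hg, correlation 0.5). Correlations and sex offsets are field-typical
defaults, configurable, since the source reports only marginals. Comorbidity
flags are conditionally independent given age, with per-year log-odds slopes
of about 0.05–0.09 (smoking negative); an explicit design simplification.

**Missingness** is missing-not-at-random by construction: the probability
that all four measurements are recorded is logit-linear in comorbidity count
(slope 0.35) and age (slope 0.01). Incomplete patients have a uniformly
chosen non-empty subset of the four measurements masked; the pre-mask values
are kept in `*_full` columns so that the generating truth is known even for
incomplete cases.

**Events.** Each patient's hazard is constant,
$\lambda_i = -m\,\ln(1-p_i)/5$ with $p_i$ the generating CHARGE-AF risk.
Because $-\ln(1-p_i) \propto \exp(lp_i)$ under the baseline-survival power
form, this is an *exact* proportional-hazards model in the linear predictor:
the calibration slope of the true linear predictor is 1 by construction for
any multiplier, which is what a well-specified-recovery test needs. (A
multiplier on the risk scale, $-\ln(1-mp_i)/5$, looks equivalent but is not:
its log-hazard is concave in $lp$, and the refit slope drops to about 0.9 at
the default calibration.) The constant-hazard shape is exchangeable with any
shape matching the same 5-year survival, since every statistic in the
pipeline depends on event times only through horizon-scale summaries.
Miscalibration knobs distort the generating linear predictor
(`lp_slope`, `lp_shift`) for power studies; an injected slope of 0.69 — a
typical overfitting regime for a risk model moved to routine-care data — is
recovered by the calibration-slope machinery (tested at $n = 20\,000$).

One published figure is knowingly *not* matched: the crude incidence rate.
The source's "4.7%" is a crude case fraction and 13.6/1000 person-years its
crude rate at 3.5 years mean follow-up; a KM 5-year cumulative incidence
consistent with both would be ≈6.4%. The generator calibrates the KM
estimate to 4.7% (the quantity the validation pipeline actually uses), so
its crude rate is ≈9.5/1000 PY. Only one of the two readings can hold at
once; the KM reading was chosen.

**Censoring** is geometric per-quarter dropout (quarter 1 always registered,
so observed time is at least 0.25 y), independent of covariates and event
times, optionally augmented with practice-level dropout blocks
(`practice_dropout_quarterly`), which cluster loss dates within practices —
the dominant loss mechanism in practice-based registries. The default leaves
practice dropout off so that the censoring distribution is exchangeable
across patients; enabling it does not change marginal follow-up calibration,
only the clustering.

`emit_raw_records()` re-expresses a cohort as the five raw tables (episodes,
measurements with decoy earlier entries, prescriptions, smoking status,
quarterly registration) so that the whole extraction pipeline can be
exercised end-to-end. The round trip recovers covariates, flags and
completeness exactly and ages as completed years; follow-up times agree to
within 0.01 years because calendar quarters are 90–92 days while the cohort
clock uses exact quarter-years.

### What passing tests do and do not show

The generator matches configured *marginals*, a single MNAR mechanism, and a
correctly specified event model. Real routine-care data differ in ways the
generator deliberately does not model: joint covariate structure beyond
age-conditional independence, coding artefacts and episode-construction
noise, model misspecification (a generator whose events come from the model
itself yields an upper bound on discrimination and a slope of 1; on real
databases the model is not the truth, discrimination is lower and slopes
well below 1 occur), non-white ethnicity, and death-as-censoring
informativeness. Green tests therefore certify the
*statistical machinery* — not that the model will perform identically on any
real database.

## Numerical choices and problem sizes

* All randomness flows from one integer seed; stage seeds are derived as
  `seed + 0..4` and every cohort carries a provenance hash of
  `(config, n, seed)`.
* Default bootstrap count is 200 resamples, percentile intervals.
* Generator fidelity is checked at $n = 100\,000$ (about 8 s); slope
  recovery at $n = 20\,000$; the goodness-of-fit type-I study runs 500
  replicates at $n = 5\,000$; oracle-equality checks use $n \le 30$ where
  brute force is exact. These sizes are the package's chosen compromise
  between Monte-Carlo error and test-suite runtime.
* Degenerate inputs fail loudly by policy: empty survival input, non-finite
  linear predictors, constant Cox covariates, unattainable calibration
  targets, risks outside (0,1).

## Known limitations

* No competing-risk (Fine–Gray) machinery; cause-specific estimates only.
* No imputation; the pipeline is complete-case by design, which is the
  estimand of interest here but not of every study.
* The shipped diagnosis/prescription code map is a placeholder for synthetic
  data, not a clinically validated operational definition.
* The categorical NRI inherits the known fragilities of category-based
  reclassification measures; it is reported because the mirrored analysis
  reports it, with the cut points made explicit.
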