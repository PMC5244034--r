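---
title: "Methods: trial-based cost-effectiveness analysis of depression prevention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness analysis of depression prevention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(prevcea)
```

`prevcea` evaluates the cost-effectiveness and cost-utility of an
indicated depression-prevention program against enhanced usual care over
a 12-month trial horizon. This vignette documents the statistical model
behind every stage, the tunable parameters and their defaults, the design
choices made where more than one reasonable convention exists, and what
the synthetic-data generator does and does not emulate. Costs and effects
are not discounted: the horizon is a single year.

## Effect measures

**Depression-free years (DFY).** The year has 365.25 days (52.18 weeks)
throughout the package; this denominator makes a censored participant
score exactly 1.0 DFY and an onset after 43 weeks score 0.824 (displayed
0.82). Onset interviews date the first day of a major depressive episode
by a life-chart calendar method; when only the week or month of onset
can be established, `resolve_onset_day()` uses the period midpoint — the
4th day of a 7-day week window and day 15 of a month window. A midpoint
is the integral of a uniform onset position over the window, and the day
rule had to be fixed by convention because "midpoint" alone does not
identify a day.

**QALYs.** `qaly_auc()` applies the trapezoid rule to linearly
interpolated utility index values at the four assessment waves (0, 6/52.18,
0.5 and 1.0 years), so a constant utility of 1 gives exactly one QALY.
The trapezoid rule is exact for a piecewise-linear function, and the test
suite verifies agreement with fine-grid numerical integration to 1e-10.
No baseline utility adjustment is applied, appropriate when baseline
utility means are balanced across arms (the generator's default makes
them equal at 0.74). Instrument floors are -0.594 (EQ-5D-3L UK tariff)
and 0.30 (SF-6D); index values are inputs — the package does not score
item responses.

Arm contrasts of DFYs and QALYs use pooled-variance independent-samples
t-tests (`arm_effect_summary()`), on the full intention-to-treat sample.

## Costing

Resource use is collected with a 3-month recall window at the baseline,
6- and 12-month waves. Quantities reported at the two follow-up waves are
scaled by the `extrapolation_factor` (default 2) so that each wave covers
its 6-month interval; the factor is configurable because any recall
extrapolation is an assumption, not an observation. Each quantity is
valued at 2013 German guideline unit prices (`unit_price_table()`):
EUR 20.92 per GP visit, 68.06 per internal-medicine consult, 46.55 per
psychiatrist and 81.44 per psychotherapist session, 335.52 and 306.41 per
in-patient day in mental-hospital and psychosomatic settings, 0.30 per
kilometre travelled, and a shadow price of 18.33 per hour of informal
care or domestic help. Productivity losses follow the human capital
approach: lost work days at the participant's gross daily wage, and
presenteeism days weighted by `1 - rating/10`, where the efficiency
rating is the participant's 0-10 self-assessment on affected days.
Antidepressant cost uses a per-day price formed from the three largest
packages of the agent: each package's statutory/private retail prices are
mixed at the statutory population share (0.89), divided by the defined
daily doses the package covers, and averaged. Program costs are
per-participant constants: EUR 299 (guided intervention) versus EUR 10
(psycho-educational control). Amounts can be indexed (factor 1.04 to the
2013 reference year) and converted to pound sterling at 0.85 GBP/EUR.

Two unit prices are not fixed by the price list and are configurable
defaults chosen once: EUR 40 per other-specialist contact
(physiotherapist/occupational-therapist scale) and EUR 150 per
psychiatric day-care day. They only set the quantity scale of the
synthetic generator — euro-level calibration targets are specified
directly — so no downstream result depends on them.

**Perspectives.** The health-care perspective totals program cost,
primary care (GP + internist), mental health care, other specialists,
in-patient care, day care, antidepressants, co-payments and
over-the-counter drugs; this composition was adopted because it is the
unique subset of categories whose control-arm means total exactly to the
control-arm health-care figure the defaults are calibrated to (EUR 768).
The societal perspective adds private therapists, informal care, domestic
help, travel and productivity losses. Participant time spent on the
program is valued (EUR 23.10/h) as its own category but excluded from
both totals by default (`include_opportunity = FALSE`), since program
time is not a standard row of either perspective; it can be switched on.
Private-therapist use enters as the participant's reported out-of-pocket
amount rather than via a unit price, because such services are paid
directly by the patient.

## Missing data

Dropout is handled by conditional-mean regression imputation
(`impute_analysis_frame()`), performed at the level of wave-specific
category costs and wave utilities, before any aggregation. For each
target, candidate baseline predictors (arm, age, sex, employment, wage,
symptom severity, baseline utilities, baseline cost) are screened twice:
against the observed target by linear regression (predictors of outcome)
and against the missingness indicator by logistic regression (predictors
of dropout, which correct for differential loss to follow-up). A
candidate is retained when its univariable coefficient has p < 0.05; the
union of both screens feeds one joint linear fit whose predictions
replace the missing values. The threshold and the univariable single-pass
form are conventions — a screening procedure needs an alpha, and
univariable screening is robust to collinear candidate sets; every
retention decision and coefficient is written to an audit log so the
analysis can be re-run under other choices. Deterministic conditional
means (no residual noise) are used deliberately: the estimand is the arm
mean, and adding noise would only inflate Monte-Carlo variance; multiple
imputation is out of scope. Observed values are never altered, and the
pass is idempotent. In-patient costs are never imputed: hospital
admissions are so rare (well under 1% of participants) that any model for
them is unstable, so missing hospital wave costs contribute zero and the
hospitalization-free sensitivity analysis bounds their influence.

## Time-to-onset analysis

`restricted_mean_survival()` integrates the Kaplan-Meier curve per arm to
52.18 weeks (the DFY denominator), with Greenwood-based standard errors;
when censoring occurs only at the horizon this equals the arm mean of
`min(onset, horizon)`, an identity the tests check to 1e-10. `fit_cox()`
compares arms by Cox proportional-hazards regression with Breslow tie
handling (week-resolution onset dates produce ties) and applies a
post-hoc pruning rule: concurrent antidepressant use is entered as a
covariate and dropped again when non-significant (p >= 0.05), refitting
the treatment-only model.

## Uncertainty analysis

Incremental cost and effect are estimated jointly by a two-equation
seemingly-unrelated-regression system — cost on treatment, effect on
treatment — by feasible generalized least squares (`fit_sur()`). With
identical regressors in both equations FGLS coincides with per-equation
OLS, so the treatment coefficients are exactly the arm differences in
means (an algebraic identity the tests enforce to 1e-8); the SUR
formulation still matters because the estimated cross-equation residual
correlation is what the bootstrap propagates into the joint (dE, dC)
cloud. `bootstrap_cea()` resamples participants with replacement,
stratified within arm so each replicate preserves the 202/204 arm sizes
and is always estimable (a pooled mode is available; with both arms
present the two modes target the same distribution). B = 2500 replicates
by default. Percentile intervals summarise incremental cost and effect.

The ICER interval cannot use plain percentiles of the ratio because the
ratio is unordered across quadrants; `icer_percentile_ci()` instead
orders replicates by angle about the origin (`atan2(dC, dE)`) and reports
the cost-to-effect ratios at the alpha/2 and 1-alpha/2 angular order
statistics. When the effect distribution straddles zero — operationally,
when the alpha/2 and 1-alpha/2 percentiles of dE bracket 0 — no ray
through the origin leaves at least alpha/2 of the mass on each side and
the interval is reported as undefined, rendered with a footnote marker in
the summary table. Quadrant shares assign dE = 0 to the east (a
measure-zero event under continuous data, fixed for reproducibility) and
dC = 0 to the south. CEACs evaluate `P(lambda * dE - dC > 0)` on a grid
of 0-50,000 EUR in steps of 50, covering all conventionally quoted
willingness-to-pay ceilings; the endpoints satisfy `p(0) = P(dC < 0)` and
`p(lambda -> infinity) -> P(dE > 0)`, which the tests verify at
lambda = 1e9. Sensitivity analyses (SF-6D QALYs instead of EQ-5D;
hospitalization costs removed) are configuration flags of the same
pipeline, not separate code paths.

Display conventions: whole euro for costs and ICERs, two decimals for
effects, whole percent for quadrant shares, one decimal for retention
percentages.

## The synthetic cohort generator

The generator (`synthetic_trial_config()`, `generate_cohort()`,
`apply_missingness()`) emulates the statistical structure the analysis
assumes, so that every downstream stage is testable without access to
patient-level trial data. Its defaults define the study conditions:

* **Arms and horizon.** 202 intervention / 204 control participants,
  365.25 days of follow-up, four assessment waves.
* **Onset.** Constant hazard per arm (exponential), censored at the
  horizon. The two hazards are solved numerically so the restricted mean
  depression-free survival equals 43 (intervention) and 37 (control)
  weeks, the calibration anchors; the implied incremental DFY is
  (43-37)/52.18 = 0.115. A constant hazard is a one-parameter stand-in —
  real onset processes are not memoryless, but only the restricted mean
  enters the economic evaluation.
* **Resource use.** Each of 17 quantity fields follows a two-part model
  per wave: a Bernoulli any-use draw (per-field zero probabilities, e.g.
  0.45 for GP visits, 0.9965 for mental-hospital days) times a gamma
  positive part (shapes 0.6-1.2), reproducing the zero inflation and
  right skew characteristic of cost data, where SDs exceed means.
  Positive-part means are solved from per-category annual euro targets —
  the default targets reproduce a published German prevention-trial cost
  table, e.g. primary care 142 vs 117, informal care 323 vs 384,
  absenteeism 1475 vs 1172 EUR — via
  `target = 2 waves x factor 2 x (1 - p0) x pos_mean x unit price`,
  with employment share and mean wage entering for productivity fields.
  Positive parts are scaled by `max(0, 1 + 0.3 z)`, where z is latent
  baseline symptom severity, so costs correlate with severity.
* **Utilities.** Truncated normals per wave with exact marginals via a
  Gaussian copula whose latent process is AR(1) with rho = 0.7 across
  waves, giving QALY variances a realistic within-person correlation
  structure. Pre-truncation locations are solved so the post-truncation
  wave means hit their targets (EQ-5D 0.74 at baseline in both arms, a
  sustained post-baseline separation sized to yield year-AUC means of
  about 0.78 vs 0.77; SF-6D 0.71 vs 0.67), and severity shifts utilities
  by -0.03 (EQ-5D) and -0.02 (SF-6D) per SD.
* **Covariates.** Age ~ 45 (SD 12), 72% female, 72% employed, gross
  daily wage lognormal with mean EUR 120 (log-SD 0.4), screening-level
  symptom scores (truncated normal over 16-60), 12% concurrent
  antidepressant use.
* **Dropout.** Monotone (once gone, gone), Bernoulli per wave with logit
  intercepts calibrated to marginal conditional dropout of 9.9%, 11.1%
  and (20.1% intervention / 3.9% control) at the three follow-up waves —
  about 90/80/70% retention with differentially higher 12-month dropout
  in the intervention arm — plus 0.4 log-odds per SD of baseline
  severity. Because severity also drives costs and utilities, dropout is
  missing-at-random given observed baseline data, which is exactly the
  mechanism regression imputation corrects; the tests confirm that
  imputed arm means have lower absolute bias than complete-case means at
  5,000 per arm. Onset interviews are treated as complete.
* **Seeding.** A single master seed with per-stream derivation
  (`substream_seed()`): participants, onset, resource use, utilities,
  dropout and each bootstrap draw from independent reproducible streams,
  so the cohort is a pure function of (config, seed).

**What the generator does not emulate:** item-level EQ-5D/SF-12
responses (index utilities are drawn directly); dependence between onset
and utilities or costs beyond the shared severity link (in particular,
onset is independent of cost residuals, so the SUR residual correlation
for the DFY analysis is near zero by construction); within-category
serial correlation of resource use across waves; seasonal or calendar
effects. Passing tests therefore demonstrate that the pipeline recovers
known truths under a realistic missingness/zero-inflation/skew structure
— not that any real intervention is cost-effective.

## Numerical choices and problem sizes

Calibration inversions (`hazard_for_restricted_mean()`,
`truncnorm_location_for_mean()`, dropout logit intercepts) use bracketed
root finding to 1e-10. Degenerate inputs are defined rather than left to
chance: zero hazard means always censored, zero incremental effect gives
an undefined ICER (NA, not an error), zero-variance bootstrap inputs
reproduce the point estimate in every replicate, and an all-zero cost
breakdown totals zero under both perspectives.

The test suite checks distributional properties at sizes chosen to make
Monte-Carlo error negligible relative to the tolerance: closed-form
restricted-mean and residual-correlation oracles at 50,000-100,000
draws, calibration of arm-level cost means at 10,000 per arm (10%
tolerance on heavily skewed categories), and full-pipeline parameter
recovery at 5,000 per arm with B = 1,000, asserting that the estimated
incremental DFY and costs fall within two bootstrap standard errors of
the configured values. The analysis scripts under `analysis/` run the
trial-scale study (406 participants, B = 2500); at that size the societal
cost contrast is dominated by rare in-patient stays and long absences, so
its sign varies across seeds — visible in the published-style percentile
intervals spanning zero — while the health-care contrast and the DFY
effect are stable.

## Known limitations

Conditional-mean imputation understates between-imputation variance; the
bootstrap partially compensates (resampling includes re-imputation error
only through the resampled completed values, not model refitting).
Fieller or bias-corrected intervals, net-benefit regression with
covariates, friction-cost productivity valuation and decision modelling
beyond the trial horizon are deliberately out of scope. The default
calibration targets are arm means; higher moments of the synthetic cost
distributions follow from the two-part gamma assumption rather than from
data.
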