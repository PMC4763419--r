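---
title: "Updating and temporally validating early trauma mortality models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Updating and temporally validating early trauma mortality models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trauma24)
```

## The problem

In a busy trauma receiving area, clinicians must decide which patients need a
repeated survey. Bedside prediction models estimate each patient's risk of
early mortality — in-hospital death within 24 hours of the first recorded
vital signs — from information available at arrival. `trauma24` implements
the full life cycle of such models in a multi-hospital registry setting:

1. **Updating.** Existing models are re-estimated on an early ("updating")
   period of the registry, and their coefficients are shrunken by a
   bootstrap-estimated linear factor to protect against overfitting.
2. **Temporal validation.** The updated models are applied unchanged to a
   later ("validation") period and compared on discrimination (AUROCC,
   sensitivity, specificity), calibration (calibration slope, risk-decile
   plots) and clinical consequences (decision curve analysis).

Missing vitals are handled by multiple imputation run separately within each
hospital, and every performance measure is pooled across imputed datasets by
its median and inter-quartile range. The flagship two-predictor model
(systolic blood pressure and Glasgow coma scale) is finally rendered as a
colour-coded bedside chart.

## The risk models

Six model structures are built in (`builtin_model()`):

| name       | terms                                                        |
|------------|--------------------------------------------------------------|
| `basic`    | 4-knot restricted cubic spline of SBP + linear GCS            |
| `basic_hr` | `basic` + 4-knot spline of heart rate                         |
| `kondo`    | linear GCS + age < 60 indicator + SBP in 3 bands              |
| `perel`    | cubic polynomials of age and SBP + quadratic GCS              |
| `sbp_only` | 4-knot SBP spline                                             |
| `gcs_only` | linear GCS                                                    |

The `kondo` and `perel` structures carry published re-estimated coefficient
sets as fixtures for arithmetic and format checks; the supported workflow is
to re-estimate all six on your own updating sample with `fit_logit()`. Two
printed conventions deserve note: the lowest SBP band of the three-band model
is taken as SBP < 60 mmHg (its published label contains an obvious extra
zero), and the interior band is closed on both sides, so 60 and 120 mmHg both
belong to it. The `perel` structure deliberately omits the original trial
model's treatment indicator and random intercept: only the fixed patient-level
terms are re-estimated.

### Restricted cubic splines

Continuous vitals enter the flexible models through a restricted cubic
spline: piecewise cubic between knots, constrained to be linear beyond the
boundary knots so that extrapolation to extreme vitals is tame. With $k$
knots $t_1 < \dots < t_k$ the basis has $k-1$ columns — the variable itself
plus, for $j = 1, \dots, k-2$,

$$f_j(x) = \frac{(x-t_j)_+^3 - (x-t_{k-1})_+^3\frac{t_k-t_j}{t_k-t_{k-1}}
  + (x-t_k)_+^3\frac{t_{k-1}-t_j}{t_k-t_{k-1}}}{(t_k-t_1)^2}.$$

Two documented choices:

* **Knot placement** defaults to equally spaced percentiles — 20/40/60/80
  for four knots (`scheme = "equal"`). The conventional outer-percentile
  scheme (5/35/65/95) is available as `scheme = "outer"`.
* **Scaling.** The nonlinear columns are divided by the squared knot range
  (the standard scaled restricted basis), which keeps their coefficients on
  a magnitude comparable to the linear term. Published coefficient tables
  rarely state their basis scaling, which is one reason printed spline
  coefficients cannot be executed directly and the structures are refitted
  instead.

Knots are computed **once**, on the updating sample, and frozen into the
model specification (`freeze_knots()`); validation and charting reuse them
unchanged. A prediction model must be fully specified before it is
validated.

## The synthetic cohort generator

The registry itself is not redistributable, so `generate_cohort()` draws
cohorts with its statistical structure, and — crucially — with a *known*
outcome model, so every downstream stage can be tested against ground truth.

What it emulates:

* **Marginals.** Age, delay from injury, SBP and heart rate are log-normal,
  parameterised directly by the target median and quartiles (age truncated
  at the eligibility bound of 15 years and rounded). Defaults reproduce the
  registry's validation-period table: SBP median 120 (IQR 110–130), HR 89
  (80–98), age 35 (25–46), delay 7 h (2–26), 80 % male, 71 % transferred,
  and the observed mechanism-of-injury mix.
* **A shock tail for SBP.** A pure log-normal matched to those quartiles has
  essentially no mass below 60 mmHg, whereas real trauma cohorts contain a
  hypotensive minority — and the three-band model structurally requires it
  (its reference band is SBP < 60). SBP is therefore a mixture: a 3 %
  haemorrhagic-shock component with median 65 (IQR 55–80) mmHg supplies the
  clinically expected tail (~1.2 % of patients below 60 mmHg) while leaving
  the overall quartiles on target.
* **GCS** is a two-component mixture: a point mass at 15 (55 % of patients)
  plus a uniform moderate/severe tail over 3–14, which reproduces a median
  of 15 with a lower quartile of 9.
* **Correlated vitals.** SBP, HR and GCS are coupled through a Gaussian
  copula. The registry reports no correlations, so defaults are a documented
  choice of mild clinical structure: lower SBP with higher HR (−0.2, shock),
  lower GCS with lower SBP (+0.3, severe injury), HR–GCS −0.1. They are
  configurable (`vitals_correlation`).
* **Outcome.** `early_death` is Bernoulli with probability from a fully
  specified logistic model shipped as a plain-text file
  (`generating_model()`): a 4-knot SBP spline (risk falling ~0.045 log-odds
  per mmHg below 100 mmHg, plateauing above 135) plus −0.25 log-odds per
  GCS point, intercept calibrated so the default cohort has ~6.8 % early
  mortality — between the registry's updating (6 %) and validation (7 %)
  rates. The implied true-model AUROCC is ≈ 0.83.
* **Missingness.** `impose_missingness()` masks only `sbp`, `hr`, `gcs` and
  `delay_h` (the fields with missingness in the registry; demographics and
  the outcome are always complete). Under MAR the masking probability
  depends only on always-observed fields — hospital, transfer status,
  mechanism — with the intercept solved numerically so the marginal rate is
  exact in expectation. `simulate_study_cohort()` applies the registry's
  period-specific rates (updating: 20/18/20/6 %; validation: 9/3/8/4 %).

What it does **not** emulate: injury-severity scores, resuscitation events,
vitals trajectories over time, hospital length of stay, or any real
between-hospital case-mix differences (hospitals differ only through the MAR
missingness model and sampling noise). Passing tests therefore demonstrate
that the *methods* are implemented correctly and behave as theory predicts
on data of this shape — not that any particular model generalises to real
patients.

Determinism: the whole generator is a pure function of its spec, including
the seed; identical specs give byte-identical cohorts.

## Imputation

`impute_cohort()` implements chained-equation multiple imputation with
predictive mean matching (PMM):

* **Per hospital.** Each hospital is imputed separately with the same
  imputation model and the completed hospitals recombined, so site-specific
  measurement practice never leaks across hospitals. Per-hospital,
  per-dataset seeds are derived deterministically from the master seed,
  which makes the separation property exactly testable: permuting other
  hospitals' rows cannot change a hospital's imputations.
* **Conditionals.** Each incomplete variable is regressed on the outcome
  (always included), age, sex, transfer status, mechanism and the other
  vitals; missing entries receive the observed value of one of the 5 donors
  whose fitted values are nearest (donor search over a sorted fitted-value
  index). PMM keeps every imputation inside the observed support — GCS stays
  an integer in 3–15, vitals stay positive — which is why it is also used
  for the ordinal coma scale. Ten burn-in cycles are run; with the modest
  missingness fractions here the chains stabilise well before that.
* **How many datasets?** `choose_m()` encodes the rule that the number of
  imputed datasets equals the percentage of incomplete observations in the
  worst-affected hospital (rounded to the nearest integer; floored at 2
  whenever anything is missing). An "incomplete observation" is a row
  missing at least one of SBP, HR, GCS or age — the variables the compared
  models need; missing delay does not count. `run_study()` defaults to a
  reduced m = 10 for speed and exposes the full rule via `m = "rule"`.
* **Pooling.** Tests are run per completed dataset and pooled as the median
  P-value with IQR (`pool_pvalues()`; median < 0.05 ⇒ significant), and
  performance metrics likewise (`pool_metric()`). Rubin's-rules variance
  pooling is intentionally out of scope: the median/IQR convention is what
  the downstream reporting uses.

## Updating and shrinkage

`fit_logit()` wraps a binomial GLM (deviance tolerance 1e-8, ≤ 100
iterations) and turns the usual silent failure modes into errors: a
single-class outcome, a rank-deficient design, or complete separation all
abort rather than returning huge coefficients. Coefficient covariance comes
from the IRLS QR decomposition, which stays stable for ill-scaled bases such
as raw cubic terms.

`bootstrap_shrinkage()` estimates a linear shrinkage factor: refit the model
in 300 bootstrap resamples (same size, with replacement); use each bootstrap
model's linear predictor in the *original* sample as the sole covariate of a
logistic regression on the outcome; average the 300 slope coefficients.
Failed bootstrap fits are redrawn (and counted); more than 10 % failures
aborts. The maximum-likelihood identity — regressing the outcome on the
model's own full-data linear predictor returns slope exactly 1 — serves as
the built-in oracle for the slope-regression substep, and the factor
approaches 1 from below as events-per-parameter grow.

`apply_shrinkage()` multiplies the non-intercept coefficients by the factor
and then, by default, re-estimates the intercept (an offset-only GLM) so the
mean predicted probability equals the observed event rate. Uniformly scaling
the intercept would distort the base rate; a literal mode
(`recalibrate_intercept = FALSE`) that scales every coefficient is provided
for comparison, since published descriptions of shrinkage are often ambiguous
on this point.

Because updating happens on imputed data, `run_study()` estimates a
shrinkage factor and shrunken coefficients on **each** imputed updating
dataset and pools the shrunken coefficient vectors by their mean (the
recorded factor is the mean factor). Shrinking a single model fitted to the
stacked imputations is a reasonable alternative; per-dataset shrinkage was
chosen because it keeps each factor attached to the fit it corrects.

## Validation, comparison, decision curves

* **AUROCC** (`auroc()`) is computed as the Mann–Whitney concordance
  probability with ties counting one half — the exact pairwise definition,
  invariant under monotone transforms.
* **Model comparison** uses the paired DeLong test for correlated ROC
  curves (`compare_auroc()`); the degenerate identical-prediction case
  returns P = 1 by convention.
* **Calibration slope** (`calibration_slope()`) is the slope of a logistic
  regression of the outcome on the linear predictor. Slope differences
  between two models on the same patients are tested by a paired bootstrap
  (`compare_calibration_slope()`, default 1000 resamples; two-sided P as
  twice the smaller tail fraction of the Δslope distribution) — an
  assumption-light choice, since no standard closed-form test exists for
  correlated calibration slopes.
* **Sensitivity/specificity** default to the 0.05 risk threshold — the same
  threshold probability highlighted in the decision-curve scenario — and are
  configurable.
* **Calibration plots** (`calibration_plot_data()`) group patients into ten
  quantile groups of predicted risk (stable ties, group sizes within one),
  and overlay a local-regression smoother (span 0.75, quadratic, on the
  probability scale) and the logistic recalibration line.
* **Decision curves** (`decision_curve()`) report net benefit
  $NB(p_t) = TP/n - (FP/n)\,p_t/(1-p_t)$ over a 0.01–0.50 threshold grid
  (step 0.01), with survey-everyone and survey-no-one baselines; ties at the
  threshold are treated as positive. Across imputations the per-dataset
  curves are pooled by the median. `net_reduction_per_100()` converts a net
  benefit advantage over treat-all into avoided unnecessary surveys per 100
  patients, reported both as the real value and truncated to an integer
  (published counts of this kind may be either truncated or rounded, so both
  are available).

## The bedside chart

`build_chart()` tabulates the two-predictor model over 10-mmHg SBP bins from
50 to 220 and GCS 3–15, with colour bands green (< 0.05), yellow
(0.05–0.20) and red (≥ 0.20) and a binary survey flag at a cutoff of 0.05.
Bin widths and band edges beyond the 0.05 anchor are conventions of this
package and are configurable. Chart cells are exact caches of
`predict_probability(linear_predictor(model, cell))` — the chart is never a
reimplementation — and `render_chart()` writes both a PNG and a lossless
text grid.

## The pipeline and its conventions

`run_study()` wires the stages together under a `study_design()`:

* **Temporal split** at a calendar date (default 2014-01-12, matching the
  default generator window of 2013-10-01 to 2014-07-23): arrivals strictly
  before midnight UTC form the updating period.
* **Event cap.** The validation sample keeps the first 200 events and every
  patient arriving up to and including the arrival *timestamp* of the
  200th event. Timestamp granularity (rather than whole days) was chosen so
  the sample contains exactly the capped number of events; with continuous
  arrival times the two conventions differ only by same-day arrivals.
* **No leakage.** Knots are frozen on the updating period's observed values;
  coefficients and shrinkage factors come from the updating imputations
  only; every emitted model file records this in its provenance field.
* **Problem sizes.** The default study runs ~4,440 patients, m = 10
  imputations per period, 300 bootstrap resamples per model per imputation,
  and 200–1000 resamples per slope comparison; a full default run completes
  in a few minutes on one core. All randomness descends from the single
  design seed, and two runs with the same seed agree byte for byte.

```{r, eval = FALSE}
sim <- simulate_study_cohort(cohort_spec(seed = 1))
report <- run_study(sim$cohort, study_design(seed = 1))
print(report)
write_report(report, "study-report")
```

## Numerical choices and degenerate inputs

* GLM convergence: deviance change < 1e-8, ≤ 100 iterations; separation is
  detected as perfect classification at machine-boundary fitted values.
* Spline knots require at least `n_knots` distinct finite values; heavily
  tied data that collapse percentiles raise an error naming the variable.
* Constant predictions collapse the calibration grouping to a single
  effective group; the loess smoother falls back to the group means when it
  cannot fit.
* `predict_probability()` is the exact inverse logit and refuses non-finite
  input; prediction on records with missing covariates is an error, never a
  silent imputation.
* PMM uses 5 donors; donor candidates are located by binary search in a
  sorted fitted-value index, so imputation scales as $O(n \log n)$.

## Known limitations

* The synthetic generator's hospitals share one case-mix; real
  between-hospital heterogeneity (and hence the value of per-hospital
  imputation) is only structurally, not distributionally, exercised.
* Published coefficient sets for the three-band and polynomial comparators
  are carried as fixtures; their original derivation cohorts are not
  emulated, so their *absolute* synthetic performance is not meaningful —
  only the machinery that updates them is under test.
* Net-benefit confidence bands, cost-weighted decision analysis, MNAR
  sensitivity analyses and Rubin's-rules pooling are out of scope.
* Late mortality and functional outcomes are not modelled.
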