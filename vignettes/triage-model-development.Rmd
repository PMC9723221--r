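---
title: "Developing and evaluating a pediatric triage risk model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and evaluating a pediatric triage risk model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedtriage)
```

## The problem and the model

In low-resource emergency departments, children can wait hours before a
clinician formally assesses them, and deterioration in that queue is a
recognised source of preventable death. A data-driven triage score
computed at first contact — from a handful of vital signs, one
anthropometric measure and a few caregiver-reported danger signs —
offers a way to move the sickest children to the front of the line.

`pedtriage` implements the full development cycle of such a score. The
core model is ordinary logistic regression of a composite admission
outcome $y$ on nine predictors:

$$\operatorname{logit} p = \beta_0
  + \beta_1\sqrt{\text{age}}
  + \beta_2\,\text{HR}
  + \beta_3\,\text{temp}
  + \beta_4\,\text{MUAC}
  + \beta_5\,\text{VS}(\text{SpO}_2)
  + \beta_6\,\text{concern}
  + \beta_7\,\text{breathing}
  + \beta_8\,\text{oedema}
  + \beta_9\,\text{pallor}$$

where age is in **months** under the square root, MUAC is the mid-upper
arm circumference in millimetres, and VS is the virtual-shunt transform
of pulse-oximetry saturation,

$$\text{VS}(s) = 70.103\,\log_{10}(101.687 - s) - 55.833,$$

a physiologic re-expression of SpO₂ as the equivalent intrapulmonary
shunt fraction. The transform linearises the relationship between
saturation and gas-exchange impairment: one point of desaturation at 85%
reflects far more derangement than one point at 99%, and feeding the raw
percentage to a linear logit would understate that. Because the offset
constant exceeds 100, the transform is finite over the whole recordable
range. `published_triage_model()` ships the deployed coefficient set as
an immutable object so the score is exactly testable; `triage_risk()`
and `score_cohort()` evaluate it on single children or batches.

## The composite outcome

Hospital admission is used as a surrogate for acuity, with two
corrections handled by `derive_outcome()`:

* admissions shorter than 24 h are treated as negative (brief
  observational admissions do not indicate severe illness);
* children sent home but readmitted to a facility within 48 h are
  positive (the triage decision they received was wrong).

`outcome_rule(count_all_admissions = TRUE)` restores the naive
"any admission" outcome as a robustness variant, and a strict-inequality
flag is available for the stay comparison; the default counts exactly
24 h as positive.

## Development procedure

The stages, each an exported function and composed by
`run_triage_pipeline()`:

1. **Imputation** (`impute_cohort`): column median for continuous,
   column mode for binary predictors, ties broken toward the smaller
   value. Statistics are computed on the full cohort before any split,
   mirroring the development analysis; leakage-free per-fold imputation
   is a straightforward variation the user can apply by imputing inside
   their own resampling loop. Disposition fields are never imputed — a
   missing length of stay for a non-admitted child is structural, not
   missing data.
2. **Events-per-variable screen** (`epv_screen`): a binary candidate is
   dropped when fewer than 10 outcome-positive children carry it. We
   interpret "events per variable" for a binary predictor as positive
   outcomes among carriers, the reading under which the rule actually
   guards the coefficient of that predictor; continuous predictors have
   no analogous count and are exempt. Both choices are recorded in the
   exclusion log.
3. **Selection** (`bootstrap_consensus`): stepwise AIC selection run on
   2,000 bootstrap resamples; predictors present in ≥ 80% of converged
   replicate selections form the consensus set. Stepwise
   (`stepwise_aic`) starts from the intercept-only model and moves
   bidirectionally; AIC ties are broken toward the smaller model, then
   lexicographically, making the procedure deterministic given the
   data. A resample containing a single outcome class is skipped and
   counted as non-converged. Starting from the full model instead is
   available via `direction = "backward"`; with candidate sets of this
   size the two starts agree on the strong predictors, and the
   intercept-only start is cheaper.
4. **Final fit** (`fit_triage_model`): maximum-likelihood logistic
   regression on the full cohort. Separation — diagnosed by
   non-convergence, runaway coefficients, or exploding Wald standard
   errors, never by small fitted probabilities alone, which are normal
   in a cohort full of well children — triggers a small ridge penalty
   (λ = 10⁻³) and a flag on the model object.
5. **Evaluation** (`evaluate_model`): stratified 10-fold
   cross-validation pools one out-of-fold risk per child into a rank
   (Mann–Whitney) AUROC, with percentile bootstrap intervals (2,000
   resamples) for the AUROC and any threshold metrics. An "80/20 split
   with 10-fold cross-validation" admits two readings; we take pooled
   10-fold CV as primary and provide repeated stratified 80/20 splits
   (`n_split_repeats`) as the secondary mode, reporting both when asked.
   Calibration uses 10 equal-count risk bins, a logistic recalibration
   fit for slope and intercept, and a bias-corrected curve that refits
   the recalibration on each of 1,000 bootstrap resamples and evaluates
   it on the original bins.
6. **Stratification** (`select_thresholds`, `build_report`): the low
   (non-urgent) boundary is the largest candidate threshold whose
   sensitivity still reaches 90% — maximising specificity subject to the
   sensitivity floor — and the high (emergency) boundary the smallest
   whose specificity reaches 90%. Categories are inclusive on the left:
   risk ≤ low is non-urgent, risk > high is emergency. Boundary metrics
   treat "at or above the category" as test-positive and are computed at
   the boundaries themselves (not at within-category summary points, a
   presentation device some reports use; metrics recomputed from our
   published confusion counts therefore match those counts exactly).
   When the boundaries cross, the report degrades gracefully to two
   categories with a warning.

All randomness flows from one master seed through derived per-stage
seeds, so a pipeline run is reproducible to the byte, as the manifest's
configuration hash certifies.

## The synthetic cohort generator

No patient-level data ships with the package, so
`generate_cohort()` produces cohorts with the structure the analysis
assumes and — crucially — a *known* generating model, making parameter
recovery, selection accuracy and calibration testable with exact truth.

* **Ages** come from a band mixture (weights 0.050, 0.393, 0.252,
  0.197, 0.089, 0.019 for <1 m, 1–12 m, 1–2 y, 2–5 y, 5–10 y, 10–15 y),
  about 89% under five.
* **Vitals and anthropometry** are age-conditional normals with means
  taken from pediatric reference ranges shifted toward an acutely ill
  population (e.g. heart rate 140 bpm in infancy falling to 90 bpm over
  ten years, SD 18; axillary temperature N(37.8, 1.1) truncated to
  [33, 43] °C; MUAC rising from 120 mm to 210 mm with age, SD 14).
  SpO₂ is 100 minus a Gamma(1.5, scale 1.8) deficit, capped to
  [50, 100] — left-skewed with ~1–2% of children under 90%.
* **Signs** are Bernoulli with prevalences 0.25 (parent concern), 0.20
  (difficulty breathing), 0.02 (oedema), 0.08 (pallor). These are
  nuisance defaults for pipeline testing, chosen once as plausible for
  this population, not claims about any cohort.
* **Outcome**: each child's latent probability is the true model (by
  default the published coefficients) on the generated predictors, with
  the intercept offset solved by root-finding so the marginal event
  rate hits the requested 22.6%. The composite outcome is the Bernoulli
  draw at that probability, and the disposition fields are then
  decomposed consistently with it: 5.2% of positives occur via the
  sent-home-then-readmitted route (yielding ≈1.5% readmissions among
  the non-admitted), the rest are admissions with stay 24 h plus an
  exponential excess (mean 62 h, putting roughly a third of long stays
  in 24–48 h), and short <24 h stays are drawn from the negatives so
  that 10% of all admissions are short. Drawing the *composite* outcome
  from the model — rather than drawing admission and layering stay and
  readmission noise on top — keeps the generating model exactly
  recoverable by the fitting stage, which is the property the
  parameter-recovery tests rely on; the alternative would attenuate
  every coefficient through label noise.
* **Missingness** is completely at random, default 2% per measured
  predictor (age and sex, being registration fields, are always
  observed).

What the generator does *not* emulate: the dozens of additional
candidate symptoms a real triage form collects, correlation between
signs and vitals beyond what the outcome model induces, seasonal or
site effects, informative missingness, and mortality (too rare to model
meaningfully). Passing tests therefore demonstrate that the machinery
is correct under the stated data-generating process, not that the
published coefficients transfer to any particular hospital.

## Numerical choices and degenerate inputs

* Stepwise accepts a move only when AIC strictly improves by more than
  10⁻⁸, preventing tie cycling.
* Threshold candidates are the observed unique risks; positivity is
  risk > threshold, matching the inclusive-left category boundaries.
* `auroc` uses midranks, so ties contribute ½ — the Mann–Whitney
  convention; the trapezoid area of `roc_curve` agrees with it to
  machine precision.
* Risks are clamped to (10⁻¹², 1 − 10⁻¹²) before logit recalibration.
* Degenerate situations warn and degrade rather than fail: an empty
  events-per-variable keep-list, a collapsed two-category
  stratification, bootstrap replicates skipped for single-class
  resamples (all logged by the pipeline).

## Problem sizes used in the tests

The shipped test-suite and acceptance script exercise the pipeline at
sizes chosen to make each claim sharp at reasonable cost: parameter
recovery at n = 50,000 (coefficient error within ±10%), consensus
selection at n = 2,000 with B = 200 replicates and ten decoys,
calibration at n = 20,000, cross-validated evaluation at the derivation
sample size n = 1,612, and unit tests at a few hundred rows. The
bootstrap default of B = 2,000 matches the development analysis;
reduced B in tests changes only Monte-Carlo precision, not the
procedure.

One property deserves honesty: with ten independent decoys, the largest
chance cohort-level association among them has a z-score around 2.3,
and a bootstrap inclusion fraction near 0.8 follows; the "no decoy
reaches 80%" expectation is therefore a knife-edge event at these
conditions, holding for some cohorts and failing for others. The
consensus threshold screens noise well, but a safety margin in the
threshold (or fewer candidates per event) is advisable in real use.

## A worked run

```{r, eval = FALSE}
cfg <- triage_run_config(
  generator = cohort_config(n_patients = 1612, seed = 1,
                            noise_predictor_count = 10),
  n_bootstrap = 200,  # 2000 in a production run
  seed = 1)
res <- run_triage_pipeline(cfg, "artifacts")
res$model
res$evaluation
res$stratification
```

## Known limitations

* The generator's marginals are stylised; effect recovery under real
  covariate structure (collinearity, informative missingness) is
  untested by construction.
* Boundary metrics are computed at the thresholds, so published tables
  built from within-category summary points will not be numerically
  identical.
* Mortality is tallied when a `died` column is present but never
  modelled.
* The ridge fallback's λ is fixed, not tuned; it exists to return
  finite, flagged estimates under separation, not to be a calibrated
  penalised model.
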