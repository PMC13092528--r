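---
title: "Methods: risk stratification and dynamic prediction of MS progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk stratification and dynamic prediction of MS progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msprogrisk)
```

## The problem

People with relapsing-remitting multiple sclerosis (RRMS) accumulate
disability at very different rates. A minority transition within a few
years to secondary progressive disease (SPMS), where most
disease-modifying therapies (DMTs) stop working; identifying that
minority early is what makes individualized 5-year risk prediction
clinically useful. This package implements two complementary predictors
over longitudinal registry data, the objective outcome definition they
are validated against, the treatment-exposure summaries they condition
on, and the validation protocol, together with a synthetic registry
generator so the whole pipeline is testable without access to patient
data.

Two progression outcomes are supported:

* **Clinical**: the neurologist's judgment of transition to SPMS,
  recorded as a dated label. It is specific but recognised late and
  inconsistently across centers.
* **Objective**: confirmed late-stage progression independent of relapse
  activity. A visit qualifies when (i) EDSS $\ge 4.0$ with pyramidal
  functional-system (FS) score $\ge 2$; (ii) the EDSS increase over the
  reference is $\ge 1.0$ when the reference EDSS is $\le 5.5$, or
  $\ge 0.5$ when it is $\ge 6$; (iii) the worsening is confirmed at
  least 90 days later, sustained in EDSS and in the leading FS at every
  intervening visit; and (iv) no relapse occurred between the preceding
  evaluation and the candidate visit. The objective definition is less
  conservative than clinical judgment, so objective events are more
  frequent than clinical labels.

### Detector conventions

The outcome definition names a required *increase* but not its
comparator. The default here is the **roving nadir**: the minimum EDSS
at or after baseline and strictly before the candidate visit. This is
the strictest commonly used reading; the baseline-visit comparator is
available through `progression_criteria(reference = "baseline")` so both
semantics are testable. The *leading functional system* is likewise
undefined in the outcome's printed form; we take the FS with the largest
increase from the reference visit to the candidate, breaking ties in the
fixed order pyramidal, cerebellar, brainstem, sensory, bowel/bladder,
visual, cerebral. Confirmation is read as *sustained*: EDSS and leading
FS may not drop below their candidate values at any visit up to and
including the first visit at least 90 days later. A candidate that needs
a missing FS score is recorded as an abstention, never silently passed
or failed; patients with abstentions fail objective-mode inclusion
(criterion I). Calendar arithmetic is in days throughout: 3 months = 90
days, 5 years = 1826 days, ages and durations are days/365.25.

## DAAE-M: a transparent 0-12 point score

The score sums integer points over four factors -- **D**isease duration,
**A**ge, **A**ge at onset, **E**DSS -- and stratifies patients into four
risk groups: very-low (0-2), low (3-7), medium (8-9), high ($\ge 10$)
for the clinical outcome. Because the objective outcome is roughly twice
as frequent, its cutoffs are adapted to 0-1 / 2-3 / 4-6 / 7-12; the
package uses these adapted cutoffs for the objective schema even though
the published objective reference table's header repeats the clinical
ones, since the adaptation is stated explicitly in the source's text.

The published per-feature point assignments live in a supplement that is
not publicly available. The package therefore ships

* `demo_weight_table()`, a clearly-labelled non-canonical demonstration
  table whose bins were chosen once from the synthetic cohort's
  covariate distributions (so all four groups are populated) with EDSS
  carrying the largest share, and
* `derive_score_weights()`, a simplified re-derivation: per-feature
  smooth logistic fits (GAM), quantile binning of each smooth effect
  with isotonic monotonisation (risk is assumed non-decreasing in each
  feature), L1-penalised selection at the one-standard-error penalty,
  and rescaling of the retained effects to non-negative integers with an
  achievable maximum of 12.

Risk is then *reported*, not refit: `lookup_risk()` serves the published
5-year risk percentages with 95% CIs by risk group, outcome, and DMT
context (unspecified; majority low/high/none over the 5-year window;
baseline low/high/none). The source tables contain no cells for DMT
switchers -- too few patients -- and the lookup raises an explicit
unsupported-context error rather than guessing. Two published contexts
are internally non-monotone across risk groups; those cells are stored
verbatim and flagged (`nonmonotone_context`) rather than smoothed. Where
the source's running text and tables disagree in the last digit, the
tabulated value is stored and the discrepancy noted in the
`daae_risk_table()` documentation. An additive DMT modifier term would
be an alternative way to fold treatment into the score; it is left
disabled because the published reports condition the *lookup* on DMT
context rather than adding points.

### Treatment exposure, two denominators

DMTs are classed low / intermediate / high efficacy by the standard
15-drug scheme (`dmt_efficacy_map()`); unknown drugs are an error, never
silently low. Episodes are half-open `[start, stop)` so a switch day is
never double counted, and overlapping records are normalized by
truncating the earlier episode at the later start.

* **DAAE-M (majority) rule**: the majority class covers strictly more
  than 50% of the 5-year window; a switch is flagged when another DMT
  class covers strictly more than 25% **of the whole window**.
* **ELIE switcher flag**: set when at least 50% of the window is treated
  and at least 25% **of treated time** is on a non-dominant class.

The two denominators are deliberately kept distinct; both appear
verbatim in the source.

### ELIE treatment-history categories

Each landmark is assigned exactly one of ten categories. Precedence, for
histories matching several patterns: never treated; stable low /
intermediate / high; bidirectional switching; escalation; de-escalation;
initiation; discontinuation; complex fallback. Two resolutions the
printed category list leaves open:

* "Stable ... with no detected switching" is read as *no transitions of
  any kind* in the window (no class-to-class, no initiation, no
  discontinuation). An untreated stretch followed by an ongoing
  first-ever DMT is therefore *initiation*, even when the drug covers
  more than half the window -- the initiation wording ("transition from
  no therapy to treated state") would otherwise be unreachable.
* Class-to-class patterns outrank initiation/discontinuation, so
  none $\to$ low $\to$ high is an escalation.

Untreated gaps shorter than `gap_tolerance_days` (default 0) between
same-class episodes are treated as registry stop/start artifacts, not
transitions.

## Propensity matching

Comparisons between majority high- and low-efficacy groups are
confounded by indication: sicker patients get stronger drugs. Propensity
scores are logistic in the four baseline covariates (age, sex, disease
duration, EDSS); matching is greedy nearest-neighbour 1:1 without
replacement on the logit of the score, no caliper, with the processing
order randomized by a declared seed and ties broken toward the lowest
control id so a run is exactly reproducible. Matching is done
cohort-wide before risk-group stratification, following the order of the
source's procedure. Balance is reported as standardized mean differences
before/after.

## ELIE: landmark construction and fit

Every eligible visit (on or after baseline, EDSS present) is a landmark.
Predictors are frozen at the landmark: age, disease duration, EDSS, age
at onset, time since baseline, and the treatment-history category over
baseline $\to$ landmark (a 1-day window stands in when the landmark *is*
the baseline). The label is 1 iff the outcome falls in the half-open
interval (landmark, landmark + 1826 d]. Visits on/after the outcome are
excluded, and event-free landmarks with less than 5 years of residual
follow-up are censored -- this censoring is what removes immortal-time
bias, and it has a visible side effect worth knowing: late landmarks of
event-free patients rarely survive it, so the retained visit-level event
fraction is much higher than the patient-level rate and
time-since-baseline carries real predictive weight.

The model is class-weighted (weights $n/(2 n_\text{class})$)
L1-penalised logistic regression. The preprocessing recipe --
training-median imputation, one-hot encoding of the ten-level category
against the never-treated reference, standardization of continuous
predictors -- is learned on training data only and stored in the model
card. The split is 80:20 *at the patient level*, the penalty is chosen
at minimum cross-validated loss over 5 patient-grouped folds (a 100-value
log-spaced grid), and refitting with the same seed reproduces the
coefficients exactly. Deciles are defined by *training*-prediction
quantiles and test rows are clamped into them; defining deciles on
pooled predictions would leak test information into the boundaries.

## Validation metrics

Observed proportions get Wilson score intervals (better small-count
coverage than Wald; checked against the exact binomial interval in the
tests). Group comparisons use the pooled two-proportion z-test (whose
square is the 2x2 chi-square without continuity correction). Calibration
tables Bonferroni-adjust over the number of strata. Discrimination uses
rank-concordance AUROC and accuracy at 0.5 (conventional after
balancing), with class-stratified percentile bootstrap CIs (default
2000 resamples). Class imbalance is corrected by SMOTE (convex
interpolation toward one of the k = 10 minority nearest neighbours)
followed by Tomek-link removal from the majority class; balancing
belongs strictly inside training folds. Missing DAAE-M features are
completed by chained equations (m = 5, 10 sweeps, predictive mean
matching with 5 donors for continuous columns, logistic draws for
binary ones, Rubin's rules for pooling); the ELIE recipe instead uses
training-median imputation, since its imputation must be part of a
frozen, portable preprocessing recipe.

## The synthetic registry

`generate_registry()` emulates the *structure* of a large adult RRMS
registry, not any empirical joint distribution: ~6-monthly visits
(SD 30 d, floor 100 d) over 2.5-7 years; baseline age Normal(37.1,
10.8) truncated to 16-75; disease duration Gamma(mean 5.8, SD 7.3);
72.6% female; baseline EDSS folded-Normal rounded to the half-point
grid (median 2, IQR about 1-3). Disease progression is a discrete-time
hazard per inter-visit interval, log-linear in standardized age,
duration and current EDSS, multiplied by the DMT-class hazard ratio in
force (high 0.45 < intermediate 0.65 < low 0.80 < untreated 1). The
intercept (-3.05 log events/year) was calibrated once so that the
clinician-labelled 5-year progression proportion in the included cohort
is close to 10%, the order of magnitude of the real cohort; labels
arrive with an Exponential (mean 6 months) recognition delay and 50%
sensitivity, so objective events outnumber clinical labels as they do in
practice. Treatment assignment carries configurable indication bias
loading on all four propensity covariates (EDSS strongly, plus age,
duration, sex), and per-year escalation / de-escalation / initiation /
discontinuation rates generate the full range of treatment histories.
EDSS evolves as a bounded half-point random walk with upward drift after
the latent progression date; pyramidal FS is forced $\ge 2$ once a
progressed patient reaches EDSS 4 so planted progressions are
detectable. Small contamination fractions (non-RRMS course, other
neurological disorder, under-18, short follow-up, MCAR missingness)
exercise every inclusion criterion.

What passing tests on this generator do **not** show: realistic
correlation structure between FS subsystems, relapse-EDSS feedback,
centre effects, informative missingness, or real-world treatment-era
effects. The generator validates the *pipeline logic* (detection,
exposure arithmetic, leakage control, calibration machinery), not
clinical transportability.

## Problem sizes and numerical choices

The test suite and the acceptance script run the end-to-end cohort at
n = 3000 patients and the rate-calibration check at n = 5000 -- sizes
chosen so binomial standard errors are small enough for 3-SE checks
while a full run stays comfortably within a desktop R session. All
randomized steps (generation, splitting, fold assignment, matching
order, bootstraps) consume explicit seeds and reproduce exactly.
Fractions of treated time are exact integer-day ratios, so the daily
brute-force oracle agrees to 1e-12; EDSS grid membership is checked with
a 1e-9 tolerance; propensity scores are clamped away from 0/1 before the
logit distance; quantile boundaries use R's default type-7 quantiles.

## Known limitations

The demonstration weight table is not the published point table; scores
from it are internally consistent but not comparable with published
scores. The re-derivation pipeline is a simplification (no literature
stage, fixed quantile knots, single isotonic direction). The landmark
formulation is a fixed-horizon binary model, not a time-to-event model;
there is no recalibration machinery across registries; and MRI and
cognitive predictors are out of scope.
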