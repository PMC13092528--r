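# msprogrisk

Individualized 5-year risk prediction of disease progression in
relapsing-remitting multiple sclerosis (RRMS), from longitudinal
clinical-registry data.

People with RRMS progress at very different rates, and most
disease-modifying therapies (DMTs) stop helping once the disease turns
secondary progressive (SPMS). This package implements, end to end, two
complementary prediction tools for clinicians and registry researchers:

* **DAAE-M** — a transparent 0–12 point score over four clinical
  factors (**D**isease duration, **A**ge, **A**ge at onset, **E**DSS),
  stratifying patients into very-low / low / medium / high risk groups
  and reporting 5-year progression risk from embedded DMT-conditional
  reference tables (by majority or baseline DMT efficacy class), with
  propensity-score matching to control indication bias in treated-group
  comparisons.
* **ELIE** — a dynamic landmark model: every clinical visit becomes a
  prediction time point, covariates are frozen at the visit, and a
  class-weighted L1-penalized logistic regression predicts the outcome
  over the following 5 years. The landmark construction (visits after
  the outcome excluded, under-followed visits censored, patient-level
  splits and patient-grouped cross-validation) is what removes
  immortal-time bias and information leakage.

Both tools support two progression outcomes: the clinician-assigned SPMS
transition, and an **objective** confirmed-progression definition (EDSS
≥ 4.0 with pyramidal functional-system score ≥ 2; EDSS increase ≥ 1.0
from a reference ≤ 5.5 or ≥ 0.5 from ≥ 6; 3-month confirmation sustained
in EDSS and leading functional system; no intervening relapse). The
package also ships the inclusion-criteria filters, DMT-exposure
classifiers (majority/switch rules and the ten ELIE treatment-history
categories), calibration and discrimination metrics (Wilson intervals,
z-tests, Brier score, AUROC, SMOTE+Tomek balancing, chained-equations
imputation), and a synthetic registry generator with known ground truth
so everything is testable without patient data.

See `vignettes/msprogrisk-methods.Rmd` for the full methods account.

## Worked example

```r
library(msprogrisk)

# a synthetic registry standing in for a real export
sim <- generate_registry(sim_config(n_patients = 400, seed = 7))
reg <- sim$registry
reg
#> MS registry: 400 patients, 4130 visits, 734 relapses, 365 treatment episodes

# inclusion filtering (A = RRMS at baseline, C = adult, E = >3y follow-up, ...)
rep <- apply_inclusion_criteria(reg, mode = "base")
table(rep$first_failed, useNA = "ifany")
#>    A    B    C    E    G <NA>
#>    3    7   12   45    7  326
cohort <- filter_registry(reg, included_ids(rep))

# DAAE-M scores and risk groups (demonstration weight table)
scores <- score_registry(cohort, outcome = "clinical")
table(scores$risk_group)
#> very_low      low   medium     high
#>       54      226       31       15

# 5-year risk for a medium-risk patient on majority high-efficacy DMT
lookup_risk("medium", "clinical", "majority_high")
#>    risk ci_low ci_high
#> 11 13.5    9.8    17.9
```

A medium-risk patient on majority high-efficacy therapy carries a 13.5%
(95% CI 9.8–17.9) 5-year risk of clinician-confirmed progression —
roughly half the 18.4% of the matched low-efficacy table cell, which is
the treatment effect the matched comparisons quantify.

```r
# ELIE: landmark dataset, patient-level split, penalized fit, validation
lm  <- build_landmark_dataset(cohort, "clinical")
sp  <- split_by_patient(lm, 0.8, seed = 7)
fit <- fit_elie(sp$train, seed = 7)
fit
#> ELIE model: 3 of 14 predictors retained (lambda = 0.0236)
pte <- predict_risk(fit, sp$test)
brier_score(pte, sp$test$outcome_label)          # 0.16
auroc_accuracy(pte, sp$test$outcome_label, n_boot = 0)$auroc  # 0.841
```

A thin command-line wrapper covers the same pipeline from a shell
(`inst/cli/msprogrisk.R`): `simulate`, `include`, `outcomes`,
`exposure`, `score`, `landmark`, `fit`, `predict`, `validate`.

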