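# hdprogress

Modifiable factors and composite-score trajectories in presymptomatic
Huntington's disease (HD).

HD mutation carriers (CAG repeats > 35) decline along trajectories shaped by
age and repeat length, but also — potentially — by factors one can act on:
education, alcohol, tobacco, coffee, BMI, psychiatric care. Studying those
factors *before* symptom onset avoids reverse causality (a behaviour changing
because the disease has begun). `hdprogress` is a reusable, tested pipeline
for that analysis, aimed at biostatisticians working with longitudinal
observational cohorts of the Enroll-HD type.

## What it computes

**Composite score.** Each visit is scored with the composite Unified
Huntington's Disease Rating Scale (lower = more advanced disease):

    cUHDRS = (TFC − 10.4)/1.9 − (TMS − 29.7)/14.9
           + (SDMT − 28.4)/11.3 + (SWR − 66.1)/20.1 + 10

**Presymptomatic staging.** A linear mixed model (random intercept + age
slope) is calibrated on family controls, adjusted for age, sex, education,
marital status, health behaviours and comorbidity count. A carrier is
presymptomatic when their baseline cUHDRS exceeds the lower bound of the 95%
prediction interval for a new control:
`ŷ − 1.96·sqrt(xᵀCov(β̂)x + zᵀDz + σ²)`. Flowchart-style filters (complete
data, above-bound baseline, no off-norm trajectory, ≥ 2 visits) with
per-rule exclusion counts reproduce the cohort-selection logic.

**Trajectory model.** A mixed-effects random forest (MERF): a regression
forest for the population surface `f(X)` over 18 fixed-effect features,
alternated (EM-style) with closed-form updates of per-subject random
effects `b_i = D Z_iᵀ V_i⁻¹ (y_i − f(X_i))`, their covariance `D`, and the
residual variance `σ²`, monitored by a generalized log-likelihood.

**Explanation.** Permutation Shapley values whose attributions sum *exactly*
to each prediction (`base_value + Σφ = f(x)`), mean-|φ| importance ranking,
Monte-Carlo Shapley interaction indices, and stratified partial dependence —
all in cUHDRS points.

**Synthetic cohort.** A generator with known ground truth emulates the
registry's structure (carrier/control arms, annual visits, nonlinear
age×CAG decline, covariate effects with the reported signs, random
intercept + slope per subject) so the whole pipeline is testable without
access to the gated data. Components are constructed so the composite
formula recovers the latent score exactly.

## Worked example

```r
library(hdprogress)

cfg <- pipeline_config(
  simulation = list(n_carriers = 250, n_controls = 250,
                    visits_min = 1, visits_max = 5,
                    missing_behavior_rate = 0.02),
  merf    = list(num_trees = 100, max_iter = 5),
  explain = list(n_explain = 30, n_background = 50,
                 n_permutations = 8, n_subsets = 8),
  seed = 7)
run_pipeline(cfg, "run1")
writeLines(pipeline_report("run1"))
```

Output (abridged) and how to read it:

```
Cohort selection (exclusions in flowchart order):
  missing_clinical         0
  below_bound              67
  missing_behavior_data    5
  off_norm_trajectory      3
  single_visit             35
  retained                 140

Decliner threshold |mean(delta/yr)| = 0.1283 cUHDRS/yr

MERF: 5 iterations; train MAE 0.273 MSE 0.121; validation MAE 0.701 MSE 0.798

Shapley importance (mean |phi|, cUHDRS points):
  age              0.2601
  cag              0.1932
  isced            0.1025
  tobacco          0.0252
  ...
  age x CAG interaction mean|phi|: 0.0550

Ground-truth recovery (planted vs recovered sign):
  tobacco          planted -1  recovered -1  (PD slope -0.0671)
  rx_dep           planted -1  recovered -1  (PD slope -0.0077)
```

Of 250 simulated carriers, 67 scored below the control-calibrated bound at
baseline (not presymptomatic) and 35 lacked follow-up; 140 enter the
trajectory analysis. The decliner threshold is recomputed from this cohort.
The MERF's subject-specific fit is tight in training and honest out of
sample. Age and CAG dominate the Shapley ranking — as planted by the
generator — with education third, and the age×CAG pair carries the largest
interaction. The recovery table confirms the planted signs of the large
covariate effects were found by the fitted forest.

Individual stages are exported too: `compute_cuhdrs()`,
`delta_cuhdrs_per_time()`, `classify_decliners()`, `fit_control_model()`,
`prediction_lower_bound()`, `apply_flowchart()`, `fit_merf()`,
`shap_values()`, `shap_interaction()`, `partial_dependence()`,
`build_table_one()`, `simulate_cohort()`.

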