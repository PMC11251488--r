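---
title: "Modelling modifiable factors in presymptomatic Huntington's disease"
author: "hdprogress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling modifiable factors in presymptomatic Huntington's disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Huntington's disease (HD) is an autosomal-dominant neurodegenerative disorder
caused by a CAG-repeat expansion in the huntingtin gene; carriers with more
than 35 repeats will develop motor, cognitive and psychiatric symptoms, with
longer expansions bringing earlier onset and faster decline. Because factors
observed after symptom onset may be consequences of the disease rather than
causes (reverse causality), the association between lifestyle factors and
progression is best studied in carriers who are still *presymptomatic*.

`hdprogress` implements that analysis end to end for longitudinal visit data:

1. **Scoring.** The composite Unified Huntington's Disease Rating Scale,
   $$\mathrm{cUHDRS} = \frac{\mathrm{TFC}-10.4}{1.9}
     - \frac{\mathrm{TMS}-29.7}{14.9}
     + \frac{\mathrm{SDMT}-28.4}{11.3}
     + \frac{\mathrm{SWR}-66.1}{20.1} + 10,$$
   combines functional capacity, motor score, and two cognitive tests into a
   single progression measure (lower = more advanced disease). Its linearity
   means group means of components map exactly to group mean scores, which
   the test suite exploits as a worked-example oracle.
2. **Staging.** A linear mixed model (random intercept and age slope per
   subject) is calibrated on *family controls*, adjusted for age, sex,
   education, marital status, health behaviours and comorbidity count. A
   carrier is presymptomatic when their baseline cUHDRS exceeds the lower
   bound of the 95% prediction interval for a new control with the same
   covariates: $\hat y - 1.96\sqrt{x^\top \widehat{\mathrm{Cov}}(\hat\beta) x
   + z^\top D z + \sigma^2}$.
3. **Trajectory modelling.** A mixed-effects random forest (MERF): a
   regression forest for the population surface $f(X)$ alternated with
   closed-form updates of per-subject random effects $b_i$ (level and age
   slope), their covariance $D$, and the residual variance $\sigma^2$.
4. **Explanation.** Permutation Shapley values with exact local accuracy,
   Monte-Carlo Shapley interaction indices, and (stratified) partial
   dependence quantify each factor's contribution in cUHDRS points.

A synthetic cohort generator with known ground truth stands in for the
application-gated registry data, so every stage is testable offline.

## The synthetic cohort generator

The generator is first-class, tested code. Its defaults are the study
conditions: ~2,600 carriers and ~2,300 family controls, 1–8 roughly annual
visits, baseline age $\mathcal N(40.16, 12.60^2)$ truncated to 18–80 (the
latent mean is shifted so the *truncated* mean matches the target), carrier
CAG a discretised $\mathcal N(41.97, 2.52^2)$ on 36–55, and covariate
marginals matched to the published descriptive table (57.5% female, mean BMI
26.0, mean ISCED 3.92, 23.5% smokers, and so on).

The latent score of a carrier visit is
$$y_{ij} = \underbrace{17.3 - A(\mathrm{CAG}_i)\,
  \mathrm{logit}^{-1}\!\left(\tfrac{\mathrm{age}_{ij} -
  m(\mathrm{CAG}_i)}{15.3}\right) + \textstyle\sum_k \beta_k x_{ik}}_{\text{fixed surface}}
  + b_{0i} + b_{1i}(\mathrm{age}_{ij} - 40) + \varepsilon_{ij},$$
with $A(c) = 7.65 + 0.88(\min(c, 47) - 42)$ and $m(c) = 78.9 - 0.31c$.
These four decline parameters were calibrated **once**, by least squares
against the published marginal partial-dependence shapes — a ~5-point drop
across ages 25–80, a ~1.7-point drop across CAG 38–47 flattening to ~0.3
across 47–55 — plus one realism anchor (a typical presymptomatic subject,
age 40 and CAG 42, sits ~1.2 points below the healthy reference). A single
logistic with a CAG-shifted midpoint cannot reproduce the saturating CAG
profile; letting the amplitude grow with CAG (saturating at 47) can, and it
also supplies the age-by-CAG interaction that the explanation stage must
recover. Controls decline linearly and mildly with age (−0.01/yr).

Covariate effects are additive with the reported signs: female +0.18,
education +0.22 per ISCED level, tobacco −0.30, antidepressant exposure
−0.34, psychiatric history −0.15, current coffee +0.06, and small terms for
the rest. The education coefficient is the one deliberate compromise: the
published summary suggests both a large education range effect (~1.8 points
from ISCED 1 to 5) *and* an importance rank below CAG; the former is a
mid-life, age-interacting effect that an additive term cannot reproduce
simultaneously with the rank. We match the importance *ordering*
(age > CAG > education), which is what the explanation-recovery tests
check.

The four components are generated to be exactly cUHDRS-consistent: TFC, TMS
and SDMT are drawn around their published means with a share of the latent
deviation, and the Stroop word-reading score is solved from the composite
identity (re-solving SDMT if the solved value leaves its plausible range).
Applying the composite formula to generated components therefore recovers
the latent score to machine precision — a free invariant for every
downstream test.

What the generator does **not** emulate: informative dropout, item-level
scores, integer rounding of real assessments, the registry's true covariate
covariance, and site effects. Passing tests therefore demonstrate that the
pipeline recovers known structure from data of this shape and noise level,
not that it would recover the same structure from the real registry.

## Staging choices

* "95% confidence interval of prediction" is read as a **prediction
  interval** for a new individual — it includes the random-effect and
  residual variance, not just the coefficient uncertainty — with a normal
  quantile (1.959964); with ~2,300 control subjects the $t$ correction is
  immaterial.
* The random-effect design centres age at the control sample mean. With raw
  age, a subject's level-at-age-0 and slope are nearly collinear and the
  intercept variance is numerically unidentifiable (it stays wherever the
  optimiser starts). Centring is a pure reparametrisation — the prediction
  variance $z^\top D z$ is unchanged — and makes `re_covariance[1,1]` the
  between-subject variance at the mean control age, the quantity the data
  actually identify.
* The selection filters run in flowchart order: complete clinical data,
  baseline score above the bound, complete behaviour data, no off-norm
  trajectory, at least two visits; each exclusion is attributed to the
  first rule that fires, and counts are conserved by construction.
* The verbal "off-norm" rule is made explicit and configurable: excluded if
  CAG > 55 with a per-subject OLS slope steeper than −2 cUHDRS/yr (very
  rapid early decline), or a positive slope despite a last visit after age
  60 (no decline despite advanced age).

## The MERF and its numerical behaviour

Each iteration (a) fits a `ranger` forest to $y - Zb$; (b) updates
$b_i = D Z_i^\top V_i^{-1}(y_i - f(X_i))$ with $V_i = Z_i D Z_i^\top +
\sigma^2 I$; (c) updates $\sigma^2$ and (d) $D$ by their closed-form EM
expressions; and records the generalized log-likelihood (GLL)
$\sum_i [\varepsilon_i^\top\varepsilon_i/\sigma^2 + b_i^\top D^{-1} b_i +
\ln|D| + n_i\ln\sigma^2]$. Defaults: 300 trees, `mtry = ceiling(p/3)`,
relative GLL tolerance $10^{-4}$, at most 30 iterations, every forest refit
seeded identically so the fit is a deterministic function of data and
configuration.

Two defaults deserve justification:

* **`min_node_size = 25`, not the usual 5.** All baseline covariates are
  constant within subject, so with 2–8 visits per subject a leaf of five
  observations can *be* one subject: the forest then memorises the random
  intercepts and $\widehat D \to 0$. Simulation shows the planted
  between-subject variance is recovered with leaves of ~25 and destroyed
  with leaves of 5. This is an identifiability requirement specific to
  longitudinal tabular data, not a tuning knob.
* **Random-effect design `[1, age − 40]`.** As in the control model, the
  subject level is defined at a reference age inside the data; defining it
  at age 0 makes $D_{00}$ an extrapolated, unidentifiable quantity.
* Scale-aware initialisation: $D$ starts at
  $\mathrm{diag}(0.1,\; 0.1/\mathrm{var}(\text{age}-40))$, so a year of
  slope is not given forty times the intercept's prior pull; $b = 0$,
  $\sigma^2 = \mathrm{var}(y)/2$. If an update leaves $D$ indefinite it is
  projected back to the PSD cone (eigenvalue floor $10^{-8}$) with a
  warning.

**The GLL trace is not monotone.** The first forest is fitted with $b = 0$
and absorbs part of the subject-level variance, so the initial residual sum
and $\sigma^2$ are spuriously small and the first recorded GLL values
undershoot. As later iterations release that variance to the random
effects, the trace relaxes *upwards* to its plateau. We verified this
behaviour across leaf sizes 5–150, in-sample and out-of-bag residuals, and
single or repeated closed-form updates per refit; it is intrinsic to the
overfit start, so the fitted object simply reports the number of
post-second-iteration increases (`gll_increases`) as a diagnostic rather
than pretending monotone descent.

**The no-random-effect limit is capacity-dependent.** With the generator's
random-effect SDs at zero, a MERF and a plain forest with the same seed
agree closely when the forest is rich (leaf 5: held-out MAE between the two
~0.02) because $b \to 0$; with deliberately weak forests (leaf 25+) the
random effects absorb the forest's smoothing bias and the two predictors
diverge even though no true random effects exist. The equivalence test in
the suite uses the high-capacity configuration on both sides.

## Explanation estimators

* **Permutation Shapley values.** For each observation, background row and
  permutation, features of the background row are replaced by the
  observation's one at a time; the attribution of a feature is the
  prediction change at its insertion. Each walk telescopes to
  $f(x) - f(r)$, and every permutation visits every background row, so
  `base_value + sum(phi)` equals $f(x)$ *exactly* — local accuracy is the
  construction, not an approximation. Permutations come in antithetic pairs
  (a permutation and its reverse), which makes two-feature attributions
  exact and reduces variance generally. Defaults: 64 pairs, 200 background
  rows. SHAP is computed on population predictions $f(X)$: random effects
  encode subject identity, not factor contributions.
* **Interaction index.** For a pair $(j,k)$, the Monte-Carlo average over
  sampled coalitions $S \not\ni j,k$ (each remaining feature enters with
  probability ½) and background rows of the second difference
  $f(S{+}j{+}k) - f(S{+}j) - f(S{+}k) + f(S)$; symmetric in the pair, zero
  in expectation for additive models, and exact for two-feature models.
* **Partial dependence.** $\mathrm{pd}(g) = \frac1n\sum_i f(x_i; x_{ij}=g)$
  on all observed levels for discrete features (≤ 10 distinct values) or up
  to 40 quantile-spaced points otherwise; optional strata (e.g. CAG below /
  at-or-above 42, BMI tertiles) partition the rows before averaging.

Tree ensembles can carry small *spurious* interactions between additively
generated features; at desk-scale cohort sizes these occasionally rival a
weakly learned true interaction on an unlucky draw. The recovery tests
therefore assert dominance of the planted age-by-CAG pair across repeated
seeded reruns rather than on any single fit.

## Decliner split and descriptive table

The per-subject change score is (last − first cUHDRS)/(last − first age) —
by definition first-to-last, not a regression slope — and the cohort
threshold is $T = |\text{mean}(\Delta/\text{yr})|$, recomputed from the
analysed cohort (−0.15 in the source study is that cohort's realised
value). The printed rule compares $|\Delta/\text{yr}|$ with $T$, which
would label a strongly *improving* subject a fast decliner; the default
uses the signed reading (slow iff $\Delta/\text{yr} \ge -T$, boundary
inclusive), with the literal absolute-value reading available via
`convention = "absolute"`. Group comparisons use Pearson's chi-squared
(no continuity correction) for categorical variables and Welch's $t$ for
continuous ones (the equal-variance variant is an option; the source states
only "t-test"). P-values are reported raw, without multiplicity correction,
as in the source table.

## Problem sizes in the test suite

The suite exercises the pipeline at desk scale, chosen as the smallest
sizes at which the checked properties are statistically stable: staging
coverage on 2,000 fitting + 2,000 held-out controls; MERF variance-component
recovery on 300 subjects × 5 visits; explanation recovery on 20 seeded
reruns of 700-carrier cohorts with 150-tree forests; and the full pipeline
on a few hundred subjects. The `run_pipeline()` defaults, by contrast, are
the full study conditions (2,600 carriers + 2,300 controls).

## Known limitations

* The generator's additive covariate effects cannot express the published
  age-varying education and BMI effects; stratified partial dependence will
  show parallel curves where the real data showed crossing ones.
* MERF variance components are recovered under the centred design; the
  level-at-birth variance of the uncentred parametrisation is not a
  recoverable quantity from adult-onset visit data and is not reported.
* The Shapley estimators use the marginal (off-manifold) expectation over
  the background; correlated covariates can receive attributions at
  feature combinations no subject exhibits.
* Exclusion counts depend on filter order (each subject is attributed to
  the first rule that fires); only the retained set is order-invariant
  when filters are independent.
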