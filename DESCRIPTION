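Package: hdprogress
Title: Modifiable Factors and Composite-Score Trajectories in
    Presymptomatic Huntington's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying modifiable factors associated with disease
    progression in presymptomatic Huntington's disease mutation carriers.
    Computes the composite Unified Huntington's Disease Rating Scale (cUHDRS)
    and time-adjusted change scores, stages carriers as presymptomatic against
    a family-control-calibrated linear mixed model's 95% prediction lower
    bound, fits a mixed-effects random forest (MERF) with per-subject random
    intercept and age slope by EM-style alternation, and explains the fitted
    forest with exactly locally accurate permutation Shapley values, Shapley
    interaction indices, and (stratified) partial dependence. A synthetic
    longitudinal cohort generator with known ground truth makes every stage
    testable without access to the application-gated Enroll-HD data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    ranger,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
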