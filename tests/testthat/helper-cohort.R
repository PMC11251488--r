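# Shared fixtures: all cohorts are generated in code at test time.

# A small all-zero-effect ground truth, handy for closed-form checks.
flat_truth <- function(level = 17, residual_sd = 0,
                       random_intercept_sd = 0, random_slope_sd = 0,
                       intercept_slope_corr = 0) {
  ground_truth(
    baseline_score = level,
    decline_amplitude = 0, amplitude_cag_slope = 0,
    control_age_slope = 0,
    coefs = c(sex = 0, isced = 0, marital = 0, residence = 0,
              alcohol_units = 0, tobacco = 0, drugs = 0, bmi = 0,
              cmb_cardio = 0, cmb_metab = 0, cmb_neuro = 0, cmb_psych = 0,
              cmb_other = 0, rx_anx = 0, rx_dep = 0),
    coffee_levels = c(0, 0, 0),
    random_intercept_sd = random_intercept_sd,
    random_slope_sd = random_slope_sd,
    intercept_slope_corr = intercept_slope_corr,
    residual_sd = residual_sd)
}

quiet_score <- function(visits) score_visits(visits, warn_range = FALSE)

# Small carrier cohort with scored visits for model-level tests.
small_cohort <- function(n = 120, seed = 1, visits_min = 3, visits_max = 5,
                         effect_spec = ground_truth()) {
  sim <- simulate_cohort(cohort_config(
    n_carriers = n, n_controls = 0, visits_min = visits_min,
    visits_max = visits_max, effect_spec = effect_spec, seed = seed))
  sim$visits <- quiet_score(sim$visits)
  sim
}
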