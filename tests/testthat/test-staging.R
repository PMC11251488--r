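# Control-calibrated mixed model, prediction lower bound, selection filters.

make_controls <- function(n, effect_spec, seed, visits_min = 2,
                          visits_max = 8) {
  sim <- simulate_cohort(cohort_config(
    n_carriers = 0, n_controls = n, visits_min = visits_min,
    visits_max = visits_max, effect_spec = effect_spec, seed = seed))
  sim$visits <- quiet_score(sim$visits)
  sim
}

test_that("prediction lower bound matches the closed form", {
  model <- structure(list(
    fixed_coefficients = c("(Intercept)" = 17, age = 0, sex = 0, isced = 0,
                           marital = 0, alcohol_units = 0, tobacco = 0,
                           coffee = 0, drugs = 0, bmi = 0, cmb_count = 0),
    coefficient_covariance = matrix(0, 11, 11),
    re_covariance = matrix(0, 2, 2),
    residual_variance = 1, age_center = 0), class = "control_lmm")
  nd <- data.frame(age = 52, sex = 1, isced = 4, marital = 1,
                   alcohol_units = 2, tobacco = 0, coffee = 1, drugs = 0,
                   bmi = 25, cmb_count = 1)
  z <- qnorm(0.975)
  out <- prediction_lower_bound(model, nd)
  expect_equal(out$lower, 17 - z, tolerance = 1e-9)

  # adding between-subject variance widens the interval: D = diag(1, 0)
  model$re_covariance <- diag(c(1, 0))
  out2 <- prediction_lower_bound(model, nd)
  expect_equal(out2$lower, 17 - z * sqrt(2), tolerance = 1e-9)

  # monotonicity: larger residual variance strictly lowers the bound
  model$residual_variance <- 2
  expect_lt(prediction_lower_bound(model, nd)$lower, out2$lower)
})

test_that("control model recovers flat-truth parameters", {
  gt <- flat_truth(level = 17, residual_sd = 1)
  sim <- make_controls(500, gt, seed = 41)
  m <- fit_control_model(sim$visits, sim$baseline)
  # fitted mean at the sample covariate means recovers the flat level
  mf <- sim$baseline
  mf$cmb_count <- mf$cmb_cardio + mf$cmb_metab + mf$cmb_neuro +
    mf$cmb_psych + mf$cmb_other
  ref <- data.frame(age = mean(sim$visits$visit_age),
                    sex = mean(mf$sex), isced = mean(mf$isced),
                    marital = mean(mf$marital),
                    alcohol_units = mean(mf$alcohol_units),
                    tobacco = mean(mf$tobacco), coffee = mean(mf$coffee),
                    drugs = mean(mf$drugs), bmi = mean(mf$bmi),
                    cmb_count = mean(mf$cmb_count))
  expect_lt(abs(prediction_lower_bound(m, ref)$fit - 17), 0.1)
  expect_gt(m$residual_variance, 0.9)
  expect_lt(m$residual_variance, 1.1)
})

test_that("between-subject variance is recovered at the reference age", {
  gt <- ground_truth(random_intercept_sd = 2)
  sim <- make_controls(500, gt, seed = 31)
  m <- fit_control_model(sim$visits, sim$baseline)
  expect_gt(m$re_covariance[1, 1], 3.2)
  expect_lt(m$re_covariance[1, 1], 4.9)
})

test_that("with one visit per subject and no random part, fit reduces to OLS", {
  gt <- flat_truth(level = 17, residual_sd = 1)
  sim <- make_controls(300, gt, seed = 43, visits_min = 1, visits_max = 1)
  m <- fit_control_model(sim$visits, sim$baseline, random = FALSE)
  mf <- hdprogress:::control_model_frame(sim$visits, sim$baseline)
  ols <- lm(cuhdrs ~ age + sex + isced + marital + alcohol_units + tobacco +
              coffee + drugs + bmi + cmb_count, mf)
  expect_equal(unname(m$fixed_coefficients), unname(coef(ols)),
               tolerance = 1e-6)
  expect_equal(unname(m$re_covariance), matrix(0, 2, 2))
})

test_that("collinear designs are rejected with the offending column named", {
  gt <- flat_truth(level = 17, residual_sd = 1)
  sim <- make_controls(50, gt, seed = 44)
  sim$baseline$alcohol_units <- 2 * sim$baseline$bmi  # planted collinearity
  expect_error(fit_control_model(sim$visits, sim$baseline), "collinear")
})

test_that("on noise-free controls the bound lies below every observed score", {
  gt <- flat_truth(level = 17, residual_sd = 0.3)
  sim <- make_controls(300, gt, seed = 45)
  m <- fit_control_model(sim$visits, sim$baseline)
  b <- sim$baseline
  ord <- order(sim$visits$subjid, sim$visits$visit_age)
  v <- sim$visits[ord, ]
  first <- v[!duplicated(v$subjid), ]
  nd <- merge(first, b, by = "subjid")
  nd$age <- nd$visit_age
  pb <- prediction_lower_bound(m, nd)
  # 95% prediction bound on well-specified data: ~2.5% below expected
  expect_lt(mean(nd$cuhdrs < pb$lower), 0.06)
})

test_that("flowchart filters exclude in order and counts are conserved", {
  sim <- small_cohort(n = 150, seed = 46, visits_min = 1, visits_max = 4)
  ctrl <- make_controls(400, ground_truth(), seed = 47)
  model <- fit_control_model(ctrl$visits, ctrl$baseline)

  # plant: one subject with missing clinical data, one with missing behaviour
  b <- sim$baseline
  b$isced[1] <- NA
  b$bmi[2] <- NA
  st <- apply_flowchart(sim$visits, b, model)
  d <- st$decisions
  expect_equal(d$exclusion_reason[d$subjid == b$subjid[1]],
               "missing_clinical")
  expect_equal(d$exclusion_reason[d$subjid == b$subjid[2]],
               "missing_behavior_data")
  expect_equal(sum(st$counts) - st$counts[["retained"]],
               sum(!d$presymptomatic))
  expect_equal(st$counts[["retained"]], sum(d$presymptomatic))
  expect_true(all(d$presymptomatic == is.na(d$exclusion_reason)))
  # below-bound exclusions carry the bound actually used
  low <- d[!is.na(d$exclusion_reason) & d$exclusion_reason == "below_bound", ]
  if (nrow(low)) expect_true(all(low$baseline_cuhdrs <= low$lower_bound))
  # single-visit subjects that survive the earlier filters are excluded last
  nv <- table(sim$visits$subjid)
  ones <- names(nv)[nv == 1]
  sv <- d[d$subjid %in% ones & is.na(match(d$exclusion_reason,
          c("missing_clinical", "below_bound", "missing_behavior_data",
            "off_norm_trajectory"))), ]
  expect_true(all(sv$exclusion_reason == "single_visit"))
})

test_that("planted off-norm trajectories are recovered exactly", {
  sim <- small_cohort(n = 80, seed = 48, visits_min = 3, visits_max = 3)
  ctrl <- make_controls(300, ground_truth(), seed = 49)
  model <- fit_control_model(ctrl$visits, ctrl$baseline)

  v <- sim$visits
  b <- sim$baseline
  ids <- unique(v$subjid)
  rapid <- ids[1:10]   # CAG 56+, slope < -2/yr
  flat_old <- ids[11:15]  # rising score despite advanced age
  b$cag[b$subjid %in% rapid] <- 56
  for (id in rapid) {
    i <- which(v$subjid == id)
    a <- v$visit_age[i]
    hi <- 17 - 2.5 * (a - min(a))
    v[i, c("tfc", "tms", "sdmt", "swr")] <-
      data.frame(tfc = 12, tms = 29.7 - 14.9 * (hi - 10 -
        (12 - 10.4) / 1.9 - 0 - 0), sdmt = 28.4, swr = 66.1)
  }
  for (id in flat_old) {
    i <- which(v$subjid == id)
    v$visit_age[i] <- 65 + (v$visit_age[i] - min(v$visit_age[i]))
    a <- v$visit_age[i]
    hi <- 15 + 0.5 * (a - min(a))
    v[i, c("tfc", "tms", "sdmt", "swr")] <-
      data.frame(tfc = 12, tms = 29.7 - 14.9 * (hi - 10 -
        (12 - 10.4) / 1.9 - 0 - 0), sdmt = 28.4, swr = 66.1)
  }
  v <- quiet_score(v[, c("subjid", "visit_age", "tfc", "tms", "sdmt", "swr")])
  st <- apply_flowchart(v, b, model)
  d <- st$decisions
  flagged <- d$subjid[!is.na(d$exclusion_reason) &
                        d$exclusion_reason == "off_norm_trajectory"]
  # every planted rapid CAG-56 decliner that reached the off-norm filter
  reached <- d$subjid[is.na(d$exclusion_reason) |
    !d$exclusion_reason %in% c("missing_clinical", "below_bound",
                               "missing_behavior_data")]
  expect_true(all(intersect(rapid, reached) %in% flagged))
  expect_true(all(intersect(flat_old, reached) %in% flagged))
  expect_false(any(setdiff(ids, c(rapid, flat_old)) %in% flagged))
})
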