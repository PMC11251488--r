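# Presymptomatic staging: control-calibrated linear mixed model, 95%
# prediction lower bound, and the cohort-selection filters.

CONTROL_MODEL_COVARIATES <- c("age", "sex", "isced", "marital",
                              "alcohol_units", "tobacco", "coffee", "drugs",
                              "bmi", "cmb_count")
BEHAVIOR_COLS <- c("alcohol_units", "tobacco", "coffee", "drugs", "bmi")
CLINICAL_COLS <- c("cag", "sex", "isced", "marital", "residence",
                   "cmb_cardio", "cmb_metab", "cmb_neuro", "cmb_psych",
                   "cmb_other", "rx_anx", "rx_dep")

# Visit-level model frame for the control mixed model.
control_model_frame <- function(visits, baseline) {
  if (!"cuhdrs" %in% names(visits)) visits <- score_visits(visits, warn_range = FALSE)
  b <- baseline
  b$cmb_count <- b$cmb_cardio + b$cmb_metab + b$cmb_neuro + b$cmb_psych +
    b$cmb_other
  i <- match(visits$subjid, b$subjid)
  if (anyNA(i)) stop("visits reference subjects absent from the baseline table")
  data.frame(subjid = visits$subjid, cuhdrs = visits$cuhdrs,
             age = visits$visit_age,
             b[i, c("sex", "isced", "marital", "alcohol_units", "tobacco",
                    "coffee", "drugs", "bmi", "cmb_count")],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the family-control-calibrated linear mixed model
#'
#' Fits, by REML, `cuhdrs ~ age + sex + education + marital + alcohol +
#' tobacco + coffee + drugs + BMI + comorbidity count + (1 + age | subject)`
#' on family-control visits. The comorbidity count is the sum of the five
#' history flags. With `random = FALSE` the random effects are dropped and
#' the model reduces to ordinary least squares (useful for single-visit
#' data).
#'
#' @param visits,baseline Control visit and baseline tables (cohort CSV
#'   schema); visits are scored on the fly if `cuhdrs` is absent.
#' @param random Include the per-subject random intercept + age slope
#'   (default `TRUE`).
#' @return Object of class `"control_lmm"`: `fixed_coefficients`,
#'   `coefficient_covariance`, `re_covariance` (2x2, intercept/age-slope;
#'   the random-effect age is centred at the control mean, see `age_center`,
#'   so the intercept variance is the between-subject variance at the mean
#'   control age), `residual_variance`, `n_subjects`, `n_visits`, and the
#'   underlying fit.
#' @export
fit_control_model <- function(visits, baseline, random = TRUE) {
  mf <- control_model_frame(visits, baseline)
  mf <- mf[stats::complete.cases(mf), , drop = FALSE]
  if (nrow(mf) < 2) stop("need at least 2 complete control visits")
  X <- stats::model.matrix(
    ~ age + sex + isced + marital + alcohol_units + tobacco + coffee +
      drugs + bmi + cmb_count, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  if (random) {
    # The random-effect design uses age centred at the control mean: with
    # raw age the per-subject level and slope are nearly collinear and the
    # intercept variance is weakly identified. Centring is a pure
    # reparametrisation; prediction_lower_bound() uses the same centring,
    # so the prediction variance is unchanged. re_covariance[1,1] is the
    # between-subject variance at the mean control age.
    age_center <- mean(mf$age)
    mf$age_c <- mf$age - age_center
    fit <- lme4::lmer(
      cuhdrs ~ age + sex + isced + marital + alcohol_units + tobacco +
        coffee + drugs + bmi + cmb_count + (1 + age_c | subjid),
      data = mf, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE))
    vc <- lme4::VarCorr(fit)
    D <- as.matrix(vc$subjid)[1:2, 1:2]
    dimnames(D) <- list(c("intercept", "age"), c("intercept", "age"))
    out <- list(fixed_coefficients = lme4::fixef(fit),
                coefficient_covariance = as.matrix(stats::vcov(fit)),
                re_covariance = D,
                residual_variance = stats::sigma(fit)^2,
                age_center = age_center,
                fit = fit)
  } else {
    fit <- stats::lm(
      cuhdrs ~ age + sex + isced + marital + alcohol_units + tobacco +
        coffee + drugs + bmi + cmb_count, data = mf)
    out <- list(fixed_coefficients = stats::coef(fit),
                coefficient_covariance = stats::vcov(fit),
                re_covariance = matrix(0, 2, 2,
                  dimnames = list(c("intercept", "age"),
                                  c("intercept", "age"))),
                residual_variance = stats::sigma(fit)^2,
                age_center = 0,
                fit = fit)
  }
  out$n_subjects <- length(unique(mf$subjid))
  out$n_visits <- nrow(mf)
  class(out) <- "control_lmm"
  out
}

#' Lower bound of the 95% prediction interval for a new individual
#'
#' For covariate row(s) `x` at age `age`, returns
#' `x' beta_hat - z_0.975 * sqrt(v)` with total variance
#' `v = x' Cov(beta_hat) x + z D z' + sigma^2` with `z = [1, age -
#' age_center]` matching the model's random-effect design: the uncertainty
#' of the fixed prediction plus the between-subject random-effect variance
#' plus residual noise. This is a prediction interval for a previously
#' unseen individual, the calibration range of "normal" control scores.
#'
#' @param model A `"control_lmm"` fit.
#' @param newdata Data frame with the baseline covariate columns of the
#'   cohort schema plus `age` (one row per prediction).
#' @return Data frame with `fit` (predicted mean), `se` (prediction SD) and
#'   `lower` (the staging bound).
#' @export
prediction_lower_bound <- function(model, newdata) {
  stopifnot(inherits(model, "control_lmm"))
  nd <- newdata
  if (!"cmb_count" %in% names(nd))
    nd$cmb_count <- nd$cmb_cardio + nd$cmb_metab + nd$cmb_neuro +
      nd$cmb_psych + nd$cmb_other
  X <- stats::model.matrix(
    ~ age + sex + isced + marital + alcohol_units + tobacco + coffee +
      drugs + bmi + cmb_count, stats::model.frame(
        ~ age + sex + isced + marital + alcohol_units + tobacco + coffee +
          drugs + bmi + cmb_count, nd, na.action = stats::na.pass))
  beta <- model$fixed_coefficients
  yhat <- drop(X %*% beta)
  vb <- rowSums((X %*% model$coefficient_covariance) * X)
  Z <- cbind(1, nd$age - model$age_center)
  vre <- rowSums((Z %*% model$re_covariance) * Z)
  v <- vb + vre + model$residual_variance
  if (any(v < 0, na.rm = TRUE)) stop("negative prediction variance (numerical)")
  z <- stats::qnorm(0.975)
  data.frame(fit = yhat, se = sqrt(v), lower = yhat - z * sqrt(v))
}

#' Apply the cohort-selection filters to mutation carriers
#'
#' Reproduces the study-selection flowchart on a carrier table, in order:
#' (1) complete sociodemographic/clinical data; (2) baseline cUHDRS above the
#' control-calibrated 95% prediction lower bound; (3) complete
#' health-behaviour data; (4) no off-norm trajectory; (5) at least two
#' visits. The off-norm rule is explicit and configurable: a carrier is
#' off-norm when `CAG > cag_max` and their per-subject OLS cUHDRS-vs-age
#' slope is steeper than `rapid_slope` (very rapid early decline), or when
#' their slope exceeds `s_max` despite last visit age above `a_min` (lack of
#' decline despite advanced age).
#'
#' @param visits,baseline Carrier visit/baseline tables.
#' @param model `"control_lmm"` fit from [fit_control_model()].
#' @param cag_max,rapid_slope,s_max,a_min Off-norm thresholds (defaults 55,
#'   -2 cUHDRS/yr, 0, 60 yr).
#' @return List of class `"staging"`: `decisions` (per-subject `subjid`,
#'   `baseline_cuhdrs`, `lower_bound`, `presymptomatic`, `exclusion_reason`)
#'   and `counts` (named exclusion counts in flowchart order plus
#'   `retained`).
#' @export
apply_flowchart <- function(visits, baseline, model,
                            cag_max = 55, rapid_slope = -2,
                            s_max = 0, a_min = 60) {
  if (!"cuhdrs" %in% names(visits)) visits <- score_visits(visits, warn_range = FALSE)
  b <- baseline
  ord <- order(visits$subjid, visits$visit_age)
  visits <- visits[ord, , drop = FALSE]
  first_idx <- !duplicated(visits$subjid)
  base_visit <- visits[first_idx, c("subjid", "visit_age", "cuhdrs")]
  i <- match(b$subjid, base_visit$subjid)
  b$baseline_age <- base_visit$visit_age[i]
  b$baseline_cuhdrs <- base_visit$cuhdrs[i]

  # per-subject OLS slope and last age, for the off-norm rule
  slopes <- vapply(split(visits[, c("visit_age", "cuhdrs")], visits$subjid),
                   function(d) {
                     if (nrow(d) < 2 || length(unique(d$visit_age)) < 2)
                       return(c(NA_real_, max(d$visit_age)))
                     c(unname(stats::coef(stats::lm(cuhdrs ~ visit_age, d))[2]),
                       max(d$visit_age))
                   }, numeric(2))
  b$slope <- slopes[1, match(b$subjid, colnames(slopes))]
  b$last_age <- slopes[2, match(b$subjid, colnames(slopes))]
  nv <- table(visits$subjid)
  b$n_visits <- as.integer(nv[match(b$subjid, names(nv))])
  b$n_visits[is.na(b$n_visits)] <- 0L

  reason <- rep(NA_character_, nrow(b))

  # (1) complete sociodemographic / clinical data
  inc_clin <- !stats::complete.cases(b[, CLINICAL_COLS, drop = FALSE]) |
    is.na(b$baseline_cuhdrs)
  reason[is.na(reason) & inc_clin] <- "missing_clinical"

  # (2) baseline score must exceed the control prediction lower bound
  nd <- b
  nd$age <- nd$baseline_age
  pb <- prediction_lower_bound(model, nd)
  b$lower_bound <- pb$lower
  below <- !is.na(b$baseline_cuhdrs) & !is.na(b$lower_bound) &
    b$baseline_cuhdrs <= b$lower_bound
  reason[is.na(reason) & below] <- "below_bound"

  # (3) complete health-behaviour data
  inc_beh <- !stats::complete.cases(b[, BEHAVIOR_COLS, drop = FALSE])
  reason[is.na(reason) & inc_beh] <- "missing_behavior_data"

  # (4) off-norm trajectories
  off <- (!is.na(b$cag) & b$cag > cag_max &
            !is.na(b$slope) & b$slope < rapid_slope) |
         (!is.na(b$slope) & b$slope > s_max &
            !is.na(b$last_age) & b$last_age > a_min)
  reason[is.na(reason) & off] <- "off_norm_trajectory"

  # (5) longitudinal follow-up
  reason[is.na(reason) & b$n_visits < 2] <- "single_visit"

  decisions <- data.frame(subjid = b$subjid,
                          baseline_cuhdrs = b$baseline_cuhdrs,
                          lower_bound = b$lower_bound,
                          presymptomatic = is.na(reason),
                          exclusion_reason = reason,
                          stringsAsFactors = FALSE)
  counts <- c(missing_clinical = sum(reason == "missing_clinical", na.rm = TRUE),
              below_bound = sum(reason == "below_bound", na.rm = TRUE),
              missing_behavior_data = sum(reason == "missing_behavior_data",
                                          na.rm = TRUE),
              off_norm_trajectory = sum(reason == "off_norm_trajectory",
                                        na.rm = TRUE),
              single_visit = sum(reason == "single_visit", na.rm = TRUE),
              retained = sum(is.na(reason)))
  structure(list(decisions = decisions, counts = counts), class = "staging")
}
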