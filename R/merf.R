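# Mixed-effects random forest: a regression forest for the fixed-effect
# surface alternated with closed-form EM updates of per-subject random
# effects (intercept + age slope), their covariance D, and the residual
# variance sigma^2, monitored by a generalized log-likelihood (GLL).

MERF_FEATURES <- c("age", "cag", "sex", "isced", "marital", "residence",
                   "alcohol_units", "tobacco", "coffee", "drugs", "bmi",
                   "cmb_cardio", "cmb_metab", "cmb_neuro", "cmb_psych",
                   "cmb_other", "rx_anx", "rx_dep")

#' Assemble the visit-level feature matrix for the MERF
#'
#' Joins baseline covariates onto visits and returns the fixed feature
#' order: age, CAG, sex, education, marital, residence, alcohol, tobacco,
#' coffee, drugs, BMI, the five comorbidity flags and the two treatment
#' flags (18 features). Rows with any missing feature or score are dropped
#' (completeness is enforced upstream by the staging filters).
#'
#' @param visits,baseline Cohort tables (visits scored on the fly if needed).
#' @return List: `X` (data frame, 18 numeric columns), `y` (cUHDRS),
#'   `subjects` (character), `age` (the random-slope timescale).
#' @export
feature_matrix <- function(visits, baseline) {
  if (!"cuhdrs" %in% names(visits)) visits <- score_visits(visits, warn_range = FALSE)
  i <- match(visits$subjid, baseline$subjid)
  if (anyNA(i)) stop("visits reference subjects absent from the baseline table")
  df <- data.frame(age = visits$visit_age,
                   baseline[i, setdiff(MERF_FEATURES, "age"), drop = FALSE],
                   row.names = NULL)
  keep <- stats::complete.cases(df) & !is.na(visits$cuhdrs)
  list(X = df[keep, MERF_FEATURES, drop = FALSE],
       y = visits$cuhdrs[keep],
       subjects = visits$subjid[keep],
       age = visits$visit_age[keep])
}

#' MERF hyperparameters and iteration controls
#'
#' @param num_trees Trees per forest (default 300).
#' @param mtry Features tried per split (default `ceiling(p/3)`).
#' @param min_node_size Minimum terminal-node size (default 25). The default
#'   is deliberately larger than in a plain regression forest: all baseline
#'   covariates are constant within subject, so small leaves can isolate the
#'   visits of a single subject and the forest then absorbs the random
#'   intercepts, destroying the identifiability of `D`. Leaves holding
#'   several subjects keep the fixed surface and the random effects
#'   separable.
#' @param max_iter Maximum EM iterations (default 30).
#' @param tol Relative GLL change declaring convergence (default 1e-4).
#' @param seed Integer seed driving every forest refit (mandatory).
#' @return List of class `"merf_control"`.
#' @export
merf_control <- function(num_trees = 300, mtry = NULL, min_node_size = 25,
                         max_iter = 30, tol = 1e-4, seed) {
  if (missing(seed)) stop("seed is mandatory")
  structure(list(num_trees = num_trees, mtry = mtry,
                 min_node_size = min_node_size, max_iter = max_iter,
                 tol = tol, seed = as.integer(seed)),
            class = "merf_control")
}

# One pass of the closed-form mixed-effect updates given forest residuals.
# r_list: per-subject (y - f(X)); Z_list: per-subject design (n_i x q).
# Returns updated b (m x q), sigma2 and D.
merf_em_step <- function(r_list, Z_list, D, sigma2) {
  m <- length(r_list)
  q <- ncol(Z_list[[1]])
  b <- matrix(0, m, q)
  N <- sum(lengths(r_list))
  sig_acc <- 0
  D_acc <- matrix(0, q, q)
  for (i in seq_len(m)) {
    Zi <- Z_list[[i]]
    ri <- r_list[[i]]
    ni <- length(ri)
    Vi <- Zi %*% D %*% t(Zi) + diag(sigma2, ni)
    Vinv <- chol2inv(chol(Vi))
    bi <- drop(D %*% t(Zi) %*% Vinv %*% ri)
    b[i, ] <- bi
    ei <- ri - drop(Zi %*% bi)
    sig_acc <- sig_acc + sum(ei^2) +
      sigma2 * (ni - sigma2 * sum(diag(Vinv)))
    D_acc <- D_acc + tcrossprod(bi) +
      (D - D %*% t(Zi) %*% Vinv %*% Zi %*% D)
  }
  list(b = b, sigma2 = sig_acc / N, D = D_acc / m)
}

# Generalized log-likelihood at the given state (lower is better).
merf_gll <- function(r_list, Z_list, b, D, sigma2) {
  Dinv <- solve_psd(D)
  logdetD <- log_det_psd(D)
  gll <- 0
  for (i in seq_along(r_list)) {
    ei <- r_list[[i]] - drop(Z_list[[i]] %*% b[i, ])
    gll <- gll + sum(ei^2) / sigma2 + drop(t(b[i, ]) %*% Dinv %*% b[i, ]) +
      logdetD + length(ei) * log(sigma2)
  }
  gll
}

# PSD-safe inverse / log-determinant with an eigenvalue floor.
solve_psd <- function(M, floor = 1e-8) {
  e <- eigen(M, symmetric = TRUE)
  v <- pmax(e$values, floor)
  e$vectors %*% (t(e$vectors) / v)
}
log_det_psd <- function(M, floor = 1e-8) {
  sum(log(pmax(eigen(M, symmetric = TRUE, only.values = TRUE)$values, floor)))
}
project_psd <- function(M, floor = 1e-8) {
  e <- eigen(M, symmetric = TRUE)
  if (all(e$values >= floor)) return(M)
  warning("random-effect covariance lost positive-definiteness; ",
          "projected to nearest PSD matrix")
  e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
}

#' Fit a mixed-effects random forest
#'
#' Alternates, until the generalized log-likelihood (GLL) stabilises or
#' `max_iter` is reached: (a) a regression forest `f` fitted to the
#' random-effect-detrended response `y - Z b`; (b) the closed-form empirical
#' BLUP update `b_i = D Z_i' V_i^{-1} (y_i - f(X_i))` with
#' `V_i = Z_i D Z_i' + sigma^2 I`; (c) the residual-variance update
#' `sigma^2 = N^{-1} sum_i [e_i'e_i + sigma^2 (n_i - sigma^2 tr(V_i^{-1}))]`;
#' (d) the covariance update
#' `D = m^{-1} sum_i [b_i b_i' + (D - D Z_i' V_i^{-1} Z_i D)]`. The GLL
#' `sum_i [e_i'e_i / sigma^2 + b_i' D^{-1} b_i + ln|D| + n_i ln sigma^2]` is
#' recorded each iteration. The random-effect design is `[1, age - 40]` per
#' visit: a subject-specific level at the reference age of 40 plus an age
#' slope (defining the level at a typical cohort age, rather than
#' extrapolated to age 0, keeps the intercept variance identifiable).
#' Every forest refit uses
#' the same seed derived from `control$seed`, so the fit is a deterministic
#' function of the data and configuration.
#'
#' @param X Data frame of fixed-effect features (see [feature_matrix()]).
#' @param y Numeric response (cUHDRS per visit).
#' @param subjects Subject id per row.
#' @param age Random-slope timescale per row (defaults to `X$age`).
#' @param control A [merf_control()] object.
#' @return Object of class `"merf"`: `forest`, `random_effects` (data frame
#'   `subjid`, `b0`, `b1`), `D`, `sigma2`, `gll_trace`, `gll_increases`
#'   (count of iterations, after the second, at which the GLL rose — logged
#'   as a diagnostic: the trace typically drops sharply and then relaxes
#'   towards its plateau), `n_iterations`, `converged`, `control`,
#'   `feature_names`.
#' @export
fit_merf <- function(X, y, subjects, age = X$age, control) {
  stopifnot(inherits(control, "merf_control"),
            nrow(X) == length(y), length(subjects) == length(y))
  if (anyNA(X) || anyNA(y)) stop("X and y must be complete (no missing values)")
  X <- as.data.frame(X)
  subjects <- as.character(subjects)
  uid <- unique(subjects)
  m <- length(uid)
  idx_list <- split(seq_along(y), factor(subjects, levels = uid))
  Z_all <- cbind(1, age - REFERENCE_AGE)
  Z_list <- lapply(idx_list, function(ix) Z_all[ix, , drop = FALSE])
  flat_age <- vapply(Z_list, function(Zi)
    nrow(Zi) > 1 && length(unique(Zi[, 2])) == 1, logical(1))
  if (any(flat_age))
    warning(sum(flat_age), " subject(s) have identical ages at all visits; ",
            "their random slopes are weakly identified")
  mtry <- if (is.null(control$mtry)) ceiling(ncol(X) / 3) else control$mtry

  b <- matrix(0, m, 2)
  # scale-aware start: the slope prior matches the intercept's contribution
  # at one age-SD, so a year of slope is not given 40x the intercept's pull
  D <- diag(c(0.1, 0.1 / max(1, stats::var(Z_all[, 2]))), 2)
  sigma2 <- stats::var(y) / 2
  if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- 1
  gll_trace <- numeric(0)
  forest <- NULL
  converged <- FALSE

  for (iter in seq_len(control$max_iter)) {
    offset <- rowSums(Z_all * b[match(subjects, uid), , drop = FALSE])
    ystar <- y - offset
    forest <- ranger::ranger(
      y = ystar, x = X,
      num.trees = control$num_trees, mtry = mtry,
      min.node.size = control$min_node_size,
      seed = control$seed, num.threads = 1)
    fhat <- stats::predict(forest, X, num.threads = 1)$predictions
    r <- y - fhat
    r_list <- lapply(idx_list, function(ix) r[ix])
    step <- merf_em_step(r_list, Z_list, D, sigma2)
    b <- step$b
    sigma2 <- max(step$sigma2, 1e-10)
    D <- project_psd((step$D + t(step$D)) / 2)
    gll_trace <- c(gll_trace, merf_gll(r_list, Z_list, b, D, sigma2))
    if (iter > 1) {
      rel <- abs(gll_trace[iter] - gll_trace[iter - 1]) /
        max(1, abs(gll_trace[iter - 1]))
      if (rel < control$tol) { converged <- TRUE; break }
    }
  }

  dimnames(D) <- list(c("intercept", "age"), c("intercept", "age"))
  d <- diff(gll_trace)
  structure(list(forest = forest,
                 random_effects = data.frame(subjid = uid, b0 = b[, 1],
                                             b1 = b[, 2],
                                             stringsAsFactors = FALSE),
                 D = D, sigma2 = sigma2, gll_trace = gll_trace,
                 gll_increases = if (length(d) > 1) sum(d[-1] > 0) else 0L,
                 n_iterations = length(gll_trace), converged = converged,
                 control = control, feature_names = names(X)),
            class = "merf")
}

#' @export
print.merf <- function(x, ...) {
  cat("Mixed-effects random forest\n")
  cat(sprintf("  %d subjects, %d features, %d trees\n",
              nrow(x$random_effects), length(x$feature_names),
              x$control$num_trees))
  cat(sprintf("  iterations: %d (%s), sigma^2 = %.4f\n", x$n_iterations,
              if (x$converged) "converged" else "max_iter reached", x$sigma2))
  cat("  D (random intercept/age-slope covariance):\n")
  print(round(x$D, 5))
  invisible(x)
}

#' Predict from a fitted MERF
#'
#' Population prediction is the forest mean `f(X)`. When `subjects` is
#' supplied, the subject-specific random effect `b0_i + b1_i * age` is added
#' for subjects seen during fitting; unseen subjects fall back to the
#' population prediction (flagged in the `"unknown_subjects"` attribute).
#'
#' @param object A `"merf"` model.
#' @param X Feature data frame (same columns as used to fit).
#' @param subjects Optional subject ids per row for subject-specific
#'   predictions.
#' @param age Random-slope timescale (defaults to `X$age`).
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.merf <- function(object, X, subjects = NULL, age = X$age, ...) {
  X <- as.data.frame(X)[, object$feature_names, drop = FALSE]
  pop <- stats::predict(object$forest, X, num.threads = 1)$predictions
  if (is.null(subjects)) return(pop)
  subjects <- as.character(subjects)
  i <- match(subjects, object$random_effects$subjid)
  unknown <- unique(subjects[is.na(i)])
  b0 <- ifelse(is.na(i), 0, object$random_effects$b0[i])
  b1 <- ifelse(is.na(i), 0, object$random_effects$b1[i])
  out <- pop + b0 + b1 * (age - REFERENCE_AGE)
  if (length(unknown)) {
    warning(length(unknown),
            " subject(s) unseen during fitting; population prediction used")
    attr(out, "unknown_subjects") <- unknown
  }
  out
}

#' Prediction error of a fitted MERF
#'
#' @param model A `"merf"` model.
#' @param X,y,subjects Evaluation partition; `subjects = NULL` evaluates the
#'   population prediction.
#' @param age Random-slope timescale (defaults to `X$age`).
#' @return List with `mae` and `mse`.
#' @export
evaluate_merf <- function(model, X, y, subjects = NULL, age = X$age) {
  if (length(y) == 0) stop("empty evaluation partition")
  pred <- predict(model, X, subjects = subjects, age = age)
  list(mae = mean(abs(y - pred)), mse = mean((y - pred)^2))
}

#' Split subjects into training and validation sets
#'
#' The split is by subject, never by visit, so no individual contributes to
#' both partitions.
#'
#' @param subjects Character vector of per-row subject ids.
#' @param frac Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return Logical vector: `TRUE` for training rows.
#' @export
split_subjects <- function(subjects, frac = 0.8, seed) {
  uid <- unique(as.character(subjects))
  old <- .Random.seed_get()
  set.seed(seed)
  train <- sample(uid, size = floor(frac * length(uid)))
  .Random.seed_set(old)
  as.character(subjects) %in% train
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(state) {
  if (!is.null(state))
    assign(".Random.seed", state, envir = globalenv())
}
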