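# Model-agnostic explanation: permutation Shapley values with exact local
# accuracy, Shapley interaction indices, and (stratified) partial
# dependence.

# Normalise a model argument to a prediction function over data frames.
as_predictor <- function(object) {
  if (is.function(object)) return(object)
  if (inherits(object, "merf"))
    return(function(X) predict(object, X))  # population prediction
  if (inherits(object, "ranger"))
    return(function(X) stats::predict(object, X, num.threads = 1)$predictions)
  stop("cannot interpret object of class ", paste(class(object), collapse = "/"),
       " as a predictor")
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  expr
}

#' Permutation Shapley values with exact local accuracy
#'
#' For every observation `x`, background row `r` and permutation `pi`, the
#' features of `r` are replaced by those of `x` one at a time in the order
#' of `pi`; the contribution of feature `j` is the prediction change when
#' `j` is inserted. Contributions along one `(r, pi)` walk sum exactly to
#' `f(x) - f(r)`, so the averaged attributions satisfy
#' `base_value + sum(phi) = f(x)` exactly (local accuracy is the estimator's
#' construction, not an approximation). Permutations are drawn in antithetic
#' pairs (each permutation and its reverse) for variance reduction; every
#' permutation visits every background row.
#'
#' For a MERF model the population prediction `f(X)` is explained: random
#' effects encode subject identity, not factor contributions.
#'
#' @param object A `"merf"` model, `ranger` forest or prediction
#'   `function(X) -> numeric`.
#' @param X Data frame of observations to explain.
#' @param background Data frame of background rows (the reference
#'   expectation); same columns as `X`.
#' @param n_permutations Number of antithetic permutation pairs (default 64).
#' @param seed Integer seed (mandatory).
#' @return Object of class `"shap_explanation"`: `base_value`, `phi`
#'   (observations x features, cUHDRS units for a cUHDRS model),
#'   `prediction` (`f(X)`), `feature_names`, `mc_config`.
#' @export
shap_values <- function(object, X, background, n_permutations = 64, seed) {
  if (missing(seed)) stop("seed is mandatory")
  f <- as_predictor(object)
  X <- as.data.frame(X)
  background <- as.data.frame(background)
  if (!identical(names(X), names(background)))
    stop("X and background must have identical feature columns")
  if (nrow(background) == 0) stop("background must be non-empty")
  stopifnot(n_permutations >= 1)
  p <- ncol(X)
  n_obs <- nrow(X)
  n_bg <- nrow(background)

  perms <- with_seed(seed, lapply(seq_len(n_permutations), function(k)
    sample.int(p)))
  perms <- c(perms, lapply(perms, rev))  # antithetic pairs

  # stacked layout: for each observation, all background rows
  obs_of_row <- rep(seq_len(n_obs), each = n_bg)
  bg_rep <- background[rep(seq_len(n_bg), times = n_obs), , drop = FALSE]
  rownames(bg_rep) <- NULL
  f_bg_rep <- f(bg_rep)
  base_value <- mean(f(background))

  phi <- matrix(0, n_obs, p, dimnames = list(NULL, names(X)))
  for (perm in perms) {
    cur <- bg_rep
    prev <- f_bg_rep
    for (j in perm) {
      cur[[j]] <- X[[j]][obs_of_row]
      pred <- f(cur)
      contrib <- pred - prev
      phi[, j] <- phi[, j] + tapply(contrib, obs_of_row, sum)
      prev <- pred
    }
  }
  phi <- phi / (length(perms) * n_bg)

  structure(list(base_value = base_value, phi = phi,
                 prediction = f(X), feature_names = names(X),
                 mc_config = list(n_permutation_pairs = n_permutations,
                                  n_background = n_bg, seed = seed)),
            class = "shap_explanation")
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat(sprintf("Shapley explanation: %d observations, %d features\n",
              nrow(x$phi), ncol(x$phi)))
  cat(sprintf("  base value (background mean prediction): %.4f\n",
              x$base_value))
  cat("  top features by mean(|phi|):\n")
  print(utils::head(importance_ranking(x), 5), row.names = FALSE)
  invisible(x)
}

#' Feature importance as mean absolute Shapley value
#'
#' @param expl A `"shap_explanation"`.
#' @return Data frame `feature`, `mean_abs_shap`, sorted descending; ties
#'   broken by original column order (stable sort).
#' @export
importance_ranking <- function(expl) {
  stopifnot(inherits(expl, "shap_explanation"))
  v <- colMeans(abs(expl$phi))
  o <- order(-v)  # stable: preserves column order on ties
  data.frame(feature = expl$feature_names[o], mean_abs_shap = unname(v[o]),
             stringsAsFactors = FALSE)
}

#' Monte-Carlo Shapley interaction index for a feature pair
#'
#' Averages, over sampled coalitions `S` excluding features `j` and `k` and
#' over background rows, the second difference
#' `f(S + j + k) - f(S + j) - f(S + k) + f(S)`, where features inside the
#' coalition take the observation's values and features outside are taken
#' from the background row. The index is symmetric in `(j, k)`; an additive
#' model has interaction 0 in expectation.
#'
#' @inheritParams shap_values
#' @param pair Length-2 vector of feature names or column indices, `j != k`.
#' @param n_subsets Coalitions evaluated per observation (default 32); drawn
#'   in antithetic pairs — each random coalition (features entering
#'   independently with probability 1/2) together with its complement.
#' @return Object of class `"shap_interaction"`: `pair`, `values`
#'   (per-observation interaction), `mean_abs`.
#' @export
shap_interaction <- function(object, X, background, pair, n_subsets = 32,
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  f <- as_predictor(object)
  X <- as.data.frame(X)
  background <- as.data.frame(background)
  if (!identical(names(X), names(background)))
    stop("X and background must have identical feature columns")
  if (is.character(pair)) pair <- match(pair, names(X))
  if (anyNA(pair) || length(pair) != 2) stop("pair must name two features")
  j <- pair[1]; k <- pair[2]
  if (j == k) stop("interaction requires two distinct features (j != k)")
  p <- ncol(X)
  rest <- setdiff(seq_len(p), c(j, k))
  n_obs <- nrow(X)
  n_bg <- nrow(background)

  # antithetic coalitions: each draw is paired with its complement, which
  # balances coalition sizes and reduces Monte-Carlo variance
  n_draw <- ceiling(n_subsets / 2)
  drawn <- with_seed(seed, lapply(seq_len(n_draw), function(s)
    rest[stats::runif(length(rest)) < 0.5]))
  subsets <- c(drawn, lapply(drawn, function(S) setdiff(rest, S)))
  n_subsets <- length(subsets)

  # one stacked design per coalition position: rows are
  # (subset x observation x background row)
  obs_of_row <- rep(rep(seq_len(n_obs), each = n_bg), times = n_subsets)
  bg_rep <- background[rep(rep(seq_len(n_bg), times = n_obs),
                           times = n_subsets), , drop = FALSE]
  rownames(bg_rep) <- NULL
  block <- n_obs * n_bg
  base <- bg_rep
  for (s in seq_len(n_subsets)) {
    rows <- (s - 1L) * block + seq_len(block)
    for (cno in subsets[[s]])
      base[[cno]][rows] <- X[[cno]][obs_of_row[rows]]
  }
  xj <- X[[j]][obs_of_row]
  xk <- X[[k]][obs_of_row]
  wj <- base; wj[[j]] <- xj
  wk <- base; wk[[k]] <- xk
  wjk <- wj; wjk[[k]] <- xk
  sec <- f(wjk) - f(wj) - f(wk) + f(base)
  values <- as.numeric(tapply(sec, obs_of_row, mean))
  structure(list(pair = names(X)[c(j, k)], values = values,
                 mean_abs = mean(abs(values)),
                 mc_config = list(n_subsets = n_subsets,
                                  n_background = n_bg, seed = seed)),
            class = "shap_interaction")
}

#' Rank all feature pairs by mean absolute Shapley interaction
#'
#' @inheritParams shap_interaction
#' @param pairs Optional list of length-2 feature-name vectors; defaults to
#'   all unordered pairs.
#' @return Data frame `feature_a`, `feature_b`, `mean_abs_interaction`,
#'   sorted descending.
#' @export
interaction_ranking <- function(object, X, background, n_subsets = 16, seed,
                                pairs = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  nm <- names(as.data.frame(X))
  if (is.null(pairs)) {
    pairs <- list()
    for (a in seq_along(nm))
      for (b in seq_along(nm))
        if (a < b) pairs[[length(pairs) + 1L]] <- c(nm[a], nm[b])
  }
  vals <- vapply(seq_along(pairs), function(i)
    shap_interaction(object, X, background, pairs[[i]],
                     n_subsets = n_subsets, seed = seed + i)$mean_abs,
    numeric(1))
  out <- data.frame(feature_a = vapply(pairs, `[`, "", 1),
                    feature_b = vapply(pairs, `[`, "", 2),
                    mean_abs_interaction = vals, stringsAsFactors = FALSE)
  out[order(-out$mean_abs_interaction), , drop = FALSE]
}

#' Partial dependence of the model prediction on one feature
#'
#' `pd(g) = mean_i f(x_i with feature := g)`: the marginal effect of the
#' feature with all other features held at their observed values. Features
#' with at most 10 distinct values (binary/ordinal covariates) use all
#' observed levels as the grid; continuous features use up to `max_grid`
#' quantile-spaced points. With `strata`, rows are partitioned and one curve
#' returned per stratum (e.g. CAG below/above the median, BMI tertiles).
#'
#' @inheritParams shap_values
#' @param feature Feature name (column of `X`).
#' @param grid Optional numeric grid (strictly increasing).
#' @param strata Optional vector (length `nrow(X)`) partitioning rows.
#' @param max_grid Maximum grid size for continuous features (default 40).
#' @return Object of class `"pd_curve"`: data frame `stratum`, `grid`, `pd`.
#' @export
partial_dependence <- function(object, X, feature, grid = NULL, strata = NULL,
                               max_grid = 40) {
  f <- as_predictor(object)
  X <- as.data.frame(X)
  if (!feature %in% names(X)) stop("feature '", feature, "' not in X")
  v <- X[[feature]]
  if (is.null(grid)) {
    u <- sort(unique(v))
    grid <- if (length(u) <= 10) u else
      sort(unique(stats::quantile(v, probs = seq(0, 1, length.out = max_grid),
                                  names = FALSE, type = 7)))
  }
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (is.null(strata)) strata <- rep("all", nrow(X))
  strata <- as.character(strata)
  groups <- split(seq_len(nrow(X)), strata)
  empty <- vapply(groups, length, 0L) == 0
  if (any(empty)) {
    warning("dropping empty stratum/strata: ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  out <- lapply(names(groups), function(g) {
    rows <- groups[[g]]
    Xg <- X[rows, , drop = FALSE]
    pd <- vapply(grid, function(gv) {
      Xg[[feature]] <- gv
      mean(f(Xg))
    }, numeric(1))
    data.frame(stratum = g, grid = grid, pd = pd, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "feature") <- feature
  class(res) <- c("pd_curve", "data.frame")
  res
}

#' @export
plot.pd_curve <- function(x, ...) {
  strata <- unique(x$stratum)
  cols <- grDevices::hcl.colors(max(3, length(strata)), "Dark 3")
  plot(NA, xlim = range(x$grid), ylim = range(x$pd),
       xlab = attr(x, "feature"), ylab = "partial dependence (cUHDRS)", ...)
  for (i in seq_along(strata)) {
    d <- x[x$stratum == strata[i], ]
    graphics::lines(d$grid, d$pd, col = cols[i], lwd = 2)
  }
  if (length(strata) > 1)
    graphics::legend("topright", legend = strata, col = cols[seq_along(strata)],
                     lwd = 2, bty = "n")
  invisible(x)
}
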