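# Permutation Shapley values, interaction index, partial dependence.

lin2 <- function(X) X$x1 + X$x2
grid2 <- function(...) data.frame(...)

test_that("additive model with zero-mean background gets exact attributions", {
  X <- grid2(x1 = c(1, -2, 0.5), x2 = c(3, 1, -1))
  bg <- grid2(x1 = c(-1, 1), x2 = c(2, -2))  # zero-mean columns
  ex <- shap_values(lin2, X, bg, n_permutations = 1, seed = 1)
  expect_equal(unname(ex$phi[, "x1"]), X$x1, tolerance = 1e-12)
  expect_equal(unname(ex$phi[, "x2"]), X$x2, tolerance = 1e-12)
  expect_equal(ex$base_value, 0, tolerance = 1e-12)
})

test_that("constant model attributes nothing", {
  X <- grid2(x1 = rnorm(4), x2 = rnorm(4))
  ex <- shap_values(function(X) rep(5, nrow(X)), X, X, n_permutations = 2,
                    seed = 2)
  expect_equal(unname(ex$phi), matrix(0, 4, 2))
  expect_equal(ex$base_value, 5)
})

test_that("pure product model splits its effect evenly (exact 2-feature Shapley)", {
  f <- function(X) X$x1 * X$x2
  ex <- shap_values(f, grid2(x1 = 1, x2 = 1), grid2(x1 = 0, x2 = 0),
                    n_permutations = 1, seed = 3)
  # antithetic pair enumerates both orders, so this is exact
  expect_equal(unname(ex$phi[1, ]), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("local accuracy is exact for a forest predictor at any seed", {
  sim <- small_cohort(n = 50, seed = 31)
  fm <- feature_matrix(sim$visits, sim$baseline)
  rf <- ranger::ranger(y = fm$y, x = fm$X, num.trees = 50, seed = 1,
                       num.threads = 1)
  for (s in c(1, 99)) {
    ex <- shap_values(rf, fm$X[1:12, ], fm$X[20:40, ], n_permutations = 3,
                      seed = s)
    gap <- ex$base_value + rowSums(ex$phi) - ex$prediction
    expect_lt(max(abs(gap)), 1e-8)
  }
})

test_that("exchangeable features receive matching importance", {
  f <- function(X) X$x1 + X$x2
  set.seed(4)
  X <- grid2(x1 = rnorm(30), x2 = rnorm(30))
  bg <- grid2(x1 = rnorm(60), x2 = rnorm(60))
  ex <- shap_values(f, X, bg, n_permutations = 8, seed = 5)
  imp <- importance_ranking(ex)
  expect_lt(abs(imp$mean_abs_shap[1] - imp$mean_abs_shap[2]), 0.12)
})

test_that("doubling permutations shrinks Monte-Carlo error roughly by sqrt(2)", {
  set.seed(6)
  # needs a 3-way interplay, otherwise antithetic pairs are already exact
  f <- function(X) X$x1 * X$x2 * X$x3
  X <- grid2(x1 = rnorm(5), x2 = rnorm(5), x3 = rnorm(5))
  bg <- grid2(x1 = rnorm(40), x2 = rnorm(40), x3 = rnorm(40))
  sd_at <- function(n_perm) {
    phis <- sapply(1:20, function(s)
      shap_values(f, X, bg, n_permutations = n_perm, seed = 100 + s)$phi[1, 1])
    sd(phis)
  }
  s1 <- sd_at(2); s2 <- sd_at(4)
  expect_lt(s2, s1)                    # more effort, less noise
  expect_lt(s2 / s1, 1.05)             # compatible with ~1/sqrt(2) decay
  expect_gt(s2 / s1, 0.3)
})

test_that("importance ranking is descending with stable tie-break", {
  phi <- matrix(0, 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  phi[, 2] <- 1
  ex <- structure(list(phi = phi, feature_names = c("a", "b", "c"),
                       base_value = 0), class = "shap_explanation")
  expect_equal(importance_ranking(ex)$feature[1], "b")
  phi[, 1] <- 1  # tie between a and b: original column order wins
  ex$phi <- phi
  expect_equal(importance_ranking(ex)$feature[1:2], c("a", "b"))
})

test_that("interaction index is exact for a product and null for additive models", {
  f <- function(X) X$x1 * X$x2
  it <- shap_interaction(f, grid2(x1 = 1, x2 = 1), grid2(x1 = 0, x2 = 0),
                         pair = c("x1", "x2"), n_subsets = 1, seed = 7)
  expect_equal(it$values, 1, tolerance = 1e-12)  # the full second difference
  # symmetry in the pair
  it2 <- shap_interaction(f, grid2(x1 = 1, x2 = 1), grid2(x1 = 0, x2 = 0),
                          pair = c("x2", "x1"), n_subsets = 1, seed = 7)
  expect_equal(it2$values, it$values)

  add <- function(X) 2 * X$x1 + 3 * X$x2 - X$x3
  set.seed(8)
  X <- grid2(x1 = rnorm(10), x2 = rnorm(10), x3 = rnorm(10))
  bg <- grid2(x1 = rnorm(30), x2 = rnorm(30), x3 = rnorm(30))
  it3 <- shap_interaction(add, X, bg, pair = c("x1", "x2"), n_subsets = 8,
                          seed = 9)
  expect_equal(it3$values, rep(0, 10), tolerance = 1e-10)
  expect_error(shap_interaction(add, X, bg, pair = c("x1", "x1"),
                                n_subsets = 2, seed = 1), "distinct")
})

test_that("partial dependence recovers closed-form marginal effects", {
  f <- function(X) 3 * X$xj + X$xk
  set.seed(10)
  X <- grid2(xj = rnorm(50), xk = rnorm(50))
  pd <- partial_dependence(f, X, "xj", grid = c(-1, 0, 1))
  expect_equal(diff(pd$pd), rep(3, 2), tolerance = 1e-9)
  # constant model: flat at the constant
  pdc <- partial_dependence(function(X) rep(4, nrow(X)), X, "xj")
  expect_true(all(pdc$pd == 4))
})

test_that("partial dependence grids respect ordinal levels and strata", {
  sim <- small_cohort(n = 40, seed = 32)
  fm <- feature_matrix(sim$visits, sim$baseline)
  f <- function(X) X$coffee + 0.1 * X$age
  pd <- partial_dependence(f, fm$X, "coffee")
  expect_equal(pd$grid, sort(unique(fm$X$coffee)))
  strata <- ifelse(fm$X$cag >= 42, "cag>=42", "cag<42")
  pds <- partial_dependence(f, fm$X, "age", strata = strata)
  expect_setequal(unique(pds$stratum), unique(strata))
  # empty strata are dropped with a warning
  strata2 <- factor(strata, levels = c("cag<42", "cag>=42", "ghost"))
  expect_warning(
    pd2 <- partial_dependence(f, fm$X, "age",
                              strata = strata2[seq_len(nrow(fm$X))],
                              grid = c(30, 50)),
    NA)  # factor collapses unused level before splitting
  expect_error(partial_dependence(f, fm$X, "nope"), "not in X")
})

test_that("a feature absent from the generating function has flat dependence", {
  f <- function(X) X$x1^2
  set.seed(11)
  X <- grid2(x1 = rnorm(60), x2 = rnorm(60))
  pd <- partial_dependence(f, X, "x2")
  expect_lt(diff(range(pd$pd)), 1e-9)
})
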