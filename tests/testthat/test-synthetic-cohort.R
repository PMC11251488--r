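# Synthetic cohort generator: determinism, composite consistency,
# marginal calibration, random-effect calibration, file round trips.

test_that("noise-free flat truth yields the configured score at every visit", {
  sim <- simulate_cohort(cohort_config(n_carriers = 20, n_controls = 20,
                                       effect_spec = flat_truth(level = 17),
                                       seed = 5))
  v <- quiet_score(sim$visits)
  expect_equal(v$cuhdrs, rep(17, nrow(v)), tolerance = 1e-9)
})

test_that("same seed reproduces the cohort bit-identically; seeds differ", {
  cfg <- cohort_config(n_carriers = 40, n_controls = 30, seed = 1)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$visits, b$visits)
  expect_identical(a$baseline, b$baseline)
  c <- simulate_cohort(cohort_config(n_carriers = 40, n_controls = 30,
                                     seed = 2))
  expect_false(identical(a$visits, c$visits))
})

test_that("components always recover the latent composite exactly", {
  sim <- small_cohort(n = 200, seed = 3)
  expect_lt(max(abs(sim$visits$cuhdrs - sim$truth$latent)), 1e-9)
  # even at extreme latents the identity holds
  gt <- flat_truth(level = 5, residual_sd = 3)
  ext <- simulate_cohort(cohort_config(n_carriers = 100, n_controls = 0,
                                       effect_spec = gt, seed = 4))
  v <- quiet_score(ext$visits)
  expect_lt(max(abs(v$cuhdrs - ext$truth$latent)), 1e-9)
})

test_that("marginals track their configured targets", {
  sim <- simulate_cohort(cohort_config(n_carriers = 2000, n_controls = 0,
                                       seed = 6))
  b <- sim$baseline
  expect_lt(abs(mean(b$bmi) - 26.01), 0.3)
  expect_lt(abs(mean(b$sex) - 0.575), 0.03)
  ages <- tapply(sim$visits$visit_age, sim$visits$subjid, min)
  expect_lt(abs(mean(ages) - 40.16), 1.0)
  expect_lt(abs(mean(b$cag) - 41.97), 0.2)
})

test_that("carrier and control CAG labelling never contradict", {
  sim <- simulate_cohort(cohort_config(n_carriers = 150, n_controls = 150,
                                       seed = 7))
  b <- sim$baseline
  expect_true(all(is.na(b$cag[b$group == "control"])))
  expect_true(all(b$cag[b$group == "carrier"] >= 36 &
                    b$cag[b$group == "carrier"] <= 55))
})

test_that("empirical random-effect SDs match the configuration within 10%", {
  gt <- flat_truth(random_intercept_sd = 1.2, random_slope_sd = 0.08,
                   residual_sd = 0.2)
  sim <- simulate_cohort(cohort_config(n_carriers = 1200, n_controls = 0,
                                       effect_spec = gt, seed = 8))
  re <- sim$truth$random_effects
  expect_lt(abs(sd(re$b0) - 1.2) / 1.2, 0.1)
  expect_lt(abs(sd(re$b1) - 0.08) / 0.08, 0.1)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_carriers = 10, n_controls = 10), "seed")
  expect_error(cohort_config(n_carriers = 10, n_controls = 10,
                             cag_values = 30:40, seed = 1), "cag_values")
  expect_error(ground_truth(intercept_slope_corr = 1.2))
  expect_error(cohort_config(n_carriers = 0, n_controls = 0, seed = 1))
})

test_that("cohort files round-trip losslessly", {
  sim <- small_cohort(n = 30, seed = 9)
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  back <- read_cohort(dir)
  expect_identical(back$visits$tfc, sim$visits$tfc)
  expect_identical(back$visits$swr, sim$visits$swr)
  expect_identical(back$visits$visit_age, sim$visits$visit_age)
  expect_identical(names(back$visits), c("subjid", "visit_age", "tfc", "tms",
                                         "sdmt", "swr"))
  expect_identical(back$baseline$bmi, sim$baseline$bmi)
  expect_identical(back$baseline$cag, sim$baseline$cag)
})

test_that("empty cohort round-trips without error", {
  dir <- withr::local_tempdir()
  empty <- list(
    visits = data.frame(subjid = character(), visit_age = numeric(),
                        tfc = numeric(), tms = numeric(), sdmt = numeric(),
                        swr = numeric()),
    baseline = simulate_cohort(cohort_config(n_carriers = 1, n_controls = 0,
                                             seed = 1))$baseline[0, ])
  write_cohort(empty, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$visits), 0)
  expect_equal(nrow(back$baseline), 0)
})

test_that("schema violations name the file, line and column", {
  dir <- withr::local_tempdir()
  sim <- small_cohort(n = 5, seed = 10)
  write_cohort(sim, dir)
  # blank participant id on the third data line
  v <- readLines(file.path(dir, "visits.csv"))
  v[4] <- sub("^[^,]*", "", v[4])
  writeLines(v, file.path(dir, "visits.csv"))
  expect_error(read_cohort(dir), "line 4.*subjid")

  write_cohort(sim, dir)
  v <- readLines(file.path(dir, "visits.csv"))
  v[3] <- sub(",[^,]*$", ",not_a_number", v[3])
  writeLines(v, file.path(dir, "visits.csv"))
  expect_error(read_cohort(dir), "line 3.*swr")

  write_cohort(sim, dir)
  b <- utils::read.csv(file.path(dir, "baseline.csv"))
  b$bmi <- NULL
  utils::write.csv(b, file.path(dir, "baseline.csv"), row.names = FALSE)
  expect_error(read_cohort(dir), "missing column.*bmi")
})
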