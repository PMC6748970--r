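test_that("point-mass calibration sets are exact and deterministic", {
  m <- point_mass_model(driver = 1, neutral = 0)
  calib <- simulate_calibration_set(m, 10, seed = 3)
  expect_equal(sum(calib$label == "driver"), 10L)
  expect_equal(sum(calib$label == "neutral"), 10L)
  expect_equal(calib$p_score[calib$label == "driver"], rep(1, 10))
  expect_equal(calib$p_score[calib$label == "neutral"], rep(0, 10))
  expect_identical(calib, simulate_calibration_set(m, 10, seed = 3))
  expect_error(simulate_calibration_set(m, 0), "positive")
})

test_that("Beta calibration draws match the analytic class means", {
  m <- class_score_model(a_pos = 8, b_pos = 2, a_neg = 2, b_neg = 8)
  n <- 50000
  calib <- simulate_calibration_set(m, n, seed = 5)
  drv <- calib$p_score[calib$label == "driver"]
  se <- sqrt(8 * 2 / ((8 + 2)^2 * (8 + 2 + 1)) / n)  # Beta variance / n
  expect_lt(abs(mean(drv) - 0.8), 3 * se)
  neu <- calib$p_score[calib$label == "neutral"]
  expect_lt(abs(mean(neu) - 0.2), 3 * se)
})

test_that("simulated cohorts conserve counts and reproduce under a seed", {
  spec <- cancer_type_spec("BRCA", 200, driver_lambda = 4, passenger_mu = 10,
                           hypermutant_fraction = 0.02)
  sim <- simulate_cohort(spec, class_score_model(), seed = 9)
  sim2 <- simulate_cohort(spec, class_score_model(), seed = 9)
  expect_identical(sim, sim2)

  # per sample: #variants = #drivers + #passengers; truth matches flags
  per_sample_records <- table(sim$records$sample_id)
  truth <- sim$truth$samples
  expect_equal(
    as.integer(per_sample_records[truth$sample_id]),
    truth$true_driver_count + truth$n_passengers)
  flagged <- tapply(sim$truth$is_driver, sim$records$sample_id, sum)
  expect_equal(as.integer(flagged[truth$sample_id]),
               truth$true_driver_count)
  # records pass the I/O validator (unique keys, domains)
  expect_silent(validate_predictions(sim$records))
})

test_that("true driver counts match the configured Poisson moments", {
  spec <- cancer_type_spec("BRCA", 10000, driver_lambda = 4,
                           passenger_mu = 0, passenger_genes = "G001")
  sim <- simulate_cohort(spec, point_mass_model(), seed = 13)
  k <- sim$truth$samples$true_driver_count
  expect_lt(abs(mean(k) - 4), 3 * sqrt(4 / 10000))
  expect_lt(abs(var(k) - 4), 4 * sqrt(2 * 4^2 / 10000) + 3 * 4 / 10000)
  # every variant is a driver when passenger_mu = 0
  expect_true(all(sim$truth$is_driver))
})

test_that("a Poisson mixture reproduces its analytic moments", {
  spec <- cancer_type_spec("COCA", 10000, driver_lambda = 2,
                           driver_lambda2 = 10, mixture_weight = 0.5,
                           passenger_mu = 0, passenger_genes = "G001")
  sim <- simulate_cohort(spec, point_mass_model(), seed = 41)
  k <- sim$truth$samples$true_driver_count
  mix_mean <- 0.5 * 2 + 0.5 * 10               # 6
  mix_var <- 6 + 0.5 * (2 - 6)^2 + 0.5 * (10 - 6)^2  # E[var] + var of means
  expect_lt(abs(mean(k) - mix_mean), 3 * sqrt(mix_var / 10000))
  expect_lt(abs(var(k) - mix_var), 0.15 * mix_var)
})

test_that("hypermutant samples always exceed 500 true drivers", {
  spec <- cancer_type_spec("SKCM", 1000, driver_lambda = 5, passenger_mu = 5,
                           hypermutant_fraction = 0.01)
  sim <- simulate_cohort(spec, class_score_model(), seed = 21)
  truth <- sim$truth$samples
  expect_gt(sum(truth$hypermutant), 0)
  expect_true(all(truth$true_driver_count[truth$hypermutant] > 500))
})

test_that("a driver-free cohort flags every variant as passenger", {
  spec <- cancer_type_spec("THCA", 100, driver_lambda = 0, passenger_mu = 50)
  sim <- simulate_cohort(spec, class_score_model(), seed = 2)
  expect_false(any(sim$truth$is_driver))
  expect_true(all(sim$truth$samples$true_driver_count == 0L))
})

test_that("stage multipliers scale driver rates and marginals are respected", {
  spec <- cancer_type_spec("PRAD", 8000, driver_lambda = 4, passenger_mu = 0,
                           passenger_genes = "G001",
                           stage_multipliers = c(I = 1, II = 1.5, III = 2,
                                                 IV = 2.5))
  sim <- simulate_cohort(spec, point_mass_model(), seed = 31)
  truth <- sim$truth$samples
  means <- tapply(truth$true_driver_count, truth$stage, mean)
  for (s in c("I", "II", "III", "IV")) {
    lam <- 4 * c(I = 1, II = 1.5, III = 2, IV = 2.5)[[s]]
    n_s <- sum(truth$stage == s)
    expect_lt(abs(means[[s]] - lam), 3 * sqrt(lam / n_s))
  }
})

test_that("the weighted-count oracle is exact for point-mass scores", {
  m <- point_mass_model(driver = 0.995, neutral = 0.005)
  calib <- simulate_calibration_set(m, 100, seed = 1)
  h <- estimate_posteriors(build_histogram(calib, 0.01), "none")
  # top bin posterior 1, bottom bin 0: oracle returns mean_drivers exactly
  expect_equal(
    expected_weighted_count_oracle(m, h, mean_drivers = 4,
                                   mean_passengers = 20), 4)
  # all bins ineligible -> 0
  h0 <- hist_with_posteriors(rep(0.4, 100))
  expect_equal(
    expected_weighted_count_oracle(m, h0, 4, 20), 0)
  # posteriors absent -> state error
  h_raw <- build_histogram(calib, 0.01)
  expect_error(expected_weighted_count_oracle(m, h_raw, 4, 20),
               "not been estimated")
})

test_that("model constructors reject invalid parameters", {
  expect_error(class_score_model(a_pos = -1), "positive")
  expect_error(cancer_type_spec("X", 10, driver_lambda = -2), "non-negative")
  expect_error(cancer_type_spec("X", 10, 1, stage_probs = c(I = 0.5, II = 0.4)),
               "sum to 1")
  expect_error(cancer_type_spec("X", 10, 1, hypermutant_fraction = 1),
               "hypermutant_fraction")
  expect_error(
    cancer_type_spec("X", 10, driver_lambda = 2, passenger_mu = 5,
                     passenger_genes = character(0)),
    "gene pool")
})
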