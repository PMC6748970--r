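make_counts <- function(values, cancer_type = "THCA", stage = NA_character_,
                        kind = "thresholded") {
  n <- length(values)
  tibble::tibble(
    sample_id = sprintf("%s_%03d", rep_len(cancer_type, n), seq_len(n)),
    cancer_type = rep_len(cancer_type, n),
    stage = rep_len(stage, n),
    region = "coding",
    n_variants = as.integer(ceiling(values) + 5),
    count_thresholded = if (kind == "thresholded") as.integer(values) else
      NA_integer_,
    count_weighted = if (kind == "weighted") as.numeric(values) else NA_real_,
    hypermutant = FALSE,
    threshold_used = if (kind == "thresholded") 0.88 else NA_real_
  )
}

test_that("per-type summaries compute mode, median, mean and quartiles", {
  s <- summarize_cohort(make_counts(c(0, 1, 1, 2, 10)))
  expect_equal(s$mode, 1)
  expect_equal(s$median, 1)
  expect_equal(s$mean, 2.8)
  expect_equal(s$n_samples, 5L)
  # mode tie broken to the smallest value
  s2 <- summarize_cohort(make_counts(c(1, 1, 2, 2)))
  expect_equal(s2$mode, 1)
  # weighted counts: mode is the midpoint of the fullest unit bin
  s3 <- summarize_cohort(make_counts(c(0.4, 1.2, 1.3), kind = "weighted"),
                         count_kind = "weighted", mode_bin_width = 1)
  expect_equal(s3$mode, 1.5)
  expect_true(all(s3$q1 <= s3$median & s3$median <= s3$q3))
})

test_that("mode and median agree for symmetric unimodal count cohorts", {
  # Poisson(16) is near-symmetric; at n = 5000 the primary mode sits within
  # one count unit of the median
  sim <- simulate_cohort(
    cancer_type_spec("X", 5000, driver_lambda = 16, passenger_mu = 0,
                     passenger_genes = "G001"),
    point_mass_model(), seed = 404)
  counts <- driver_counts(sim$records, threshold = 0.5,
                          samples = sim$truth$samples)
  s <- summarize_cohort(counts)
  expect_lte(abs(s$mode - s$median), 1)
})

test_that("threshold sweeps recompute counts and the filter at each point", {
  sim <- simulate_cohort(
    cohort_model(
      cancer_type_spec("A", 20, driver_lambda = 5, passenger_mu = 10),
      cancer_type_spec("B", 20, driver_lambda = 1, passenger_mu = 10)),
    class_score_model(), seed = 19)
  # threshold 0: every variant counts, medians equal medians of n_variants
  sw0 <- sweep_thresholds(sim$records, grid = 0)
  nv <- sim$records |> dplyr::count(.data$cancer_type, .data$sample_id)
  med_nv <- tapply(nv$n, nv$cancer_type, median)
  expect_equal(sw0$median, as.numeric(med_nv[sw0$cancer_type]))
  # threshold 1 with all scores < 1: all medians 0
  sw1 <- sweep_thresholds(sim$records, grid = 1)
  expect_true(all(sw1$median == 0))
  # per-type mean and median curves are non-increasing over the grid
  sw <- sweep_thresholds(sim$records, grid = seq(0, 1, by = 0.05))
  for (ct in c("A", "B")) {
    expect_true(all(diff(sw$mean[sw$cancer_type == ct]) <= 1e-9))
    expect_true(all(diff(sw$median[sw$cancer_type == ct]) <= 1e-9))
  }
  expect_error(sweep_thresholds(sim$records, numeric(0)), "empty")
})

test_that("exact Mann-Whitney p-values come from full enumeration", {
  counts <- dplyr::bind_rows(make_counts(c(1, 2), "X"),
                             make_counts(c(3, 4), "Y"))
  res <- mann_whitney_vs_rest(counts, "X")
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 2 / 6)
  expect_equal(res$method, "exact")
  # identical multisets: maximal symmetry, p = 1
  counts2 <- dplyr::bind_rows(make_counts(c(1, 2, 3), "X"),
                              make_counts(c(1, 2, 3), "Y"))
  expect_equal(mann_whitney_vs_rest(counts2, "X")$p_value, 1)
  # empty rest pool errors
  expect_error(mann_whitney_vs_rest(make_counts(1:3, "X"), "X"),
               "rest pool is empty")
  expect_error(mann_whitney_vs_rest(counts, "Z"), "no samples")
})

test_that("exact enumeration agrees with wilcox.test on tie-free cases", {
  set.seed(101)
  for (i in 1:10) {
    x <- sample(1:100, 5)
    y <- sample(setdiff(1:100, x), 5)
    counts <- dplyr::bind_rows(make_counts(x, "X"), make_counts(y, "Y"))
    res <- mann_whitney_vs_rest(counts, "X")
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(res$p_value, ref$p.value)
    expect_equal(res$U, unname(ref$statistic))
  }
})

test_that("the normal approximation tracks exact enumeration at n = 6 + 6", {
  set.seed(202)
  for (i in 1:10) {
    x <- sample(1:1000, 6)
    y <- sample(setdiff(1:1000, x), 6)
    p_exact <- driverburden:::mw_exact_p(x, y)
    p_norm <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("large cohorts switch to the normal approximation", {
  counts <- dplyr::bind_rows(make_counts(rpois(50, 1), "X"),
                             make_counts(rpois(100, 8), "Y"))
  res <- mann_whitney_vs_rest(counts, "X")
  expect_equal(res$method, "normal_approx")
  expect_lt(res$p_value, 1e-6)
  expect_true(res$U >= 0 && res$U <= res$n_type * res$n_rest)
})

test_that("stage stratification tabulates quartiles and median monotonicity", {
  counts <- dplyr::bind_rows(
    make_counts(c(1, 2, 3, 4), "X", stage = "I"),
    make_counts(c(2, 3, 4, 5), "X", stage = "II"),
    make_counts(c(4, 5, 6, 7), "X", stage = "III"))
  st <- stratify_by_stage(counts)
  s1 <- st[st$stage == "I", ]
  expect_equal(s1$mean, 2.5)
  expect_equal(s1$q1, 1.75)
  expect_equal(s1$median, 2.5)
  expect_equal(s1$q3, 3.25)
  expect_true(all(st$monotone_medians))
  # a stage dip flips the flag
  counts2 <- dplyr::bind_rows(
    make_counts(c(5, 6, 7), "X", stage = "I"),
    make_counts(c(1, 2, 3), "X", stage = "II"))
  expect_false(any(stratify_by_stage(counts2)$monotone_medians))
  # unknown stages are excluded with a tally; all-unknown warns and is empty
  counts3 <- dplyr::bind_rows(counts, make_counts(100, "X"))
  expect_message(st3 <- stratify_by_stage(counts3), "excluding 1 samples")
  expect_equal(st3[st3$stage == "I", ]$median, 2.5)
  expect_warning(st4 <- stratify_by_stage(make_counts(1:5, "X")),
                 "no samples with known stage")
  expect_equal(nrow(st4), 0L)
})

test_that("stages with no samples are omitted, not zero-filled", {
  counts <- dplyr::bind_rows(
    make_counts(c(1, 2, 3), "X", stage = "I"),
    make_counts(c(2, 3, 4), "X", stage = "IV"))
  st <- stratify_by_stage(counts)
  expect_equal(st$stage, c("I", "IV"))
})
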