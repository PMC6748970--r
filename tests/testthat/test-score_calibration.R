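test_that("histogram binning follows the half-open rule with 1 closed", {
  calib <- make_calibration(c(0.905, 0.915, 1.0), 0.905)
  h <- build_histogram(calib, bin_width = 0.01)
  expect_length(h$pos_counts, 100L)
  expect_equal(h$pos_counts[91], 1L)  # [0.90, 0.91): one driver
  expect_equal(h$neg_counts[91], 1L)
  expect_equal(h$pos_counts[92], 1L)  # [0.91, 0.92): one driver
  expect_equal(h$neg_counts[92], 0L)
  expect_equal(h$pos_counts[100], 1L)  # exact 1.0 in the last bin
  expect_equal(sum(h$pos_counts), 3L)
  expect_equal(sum(h$neg_counts), 1L)

  # bin-edge scores land in the bin they open
  h2 <- build_histogram(make_calibration(c(0.91, 0.9999999999), 0.0), 0.01)
  expect_equal(h2$pos_counts[92], 1L)
  expect_equal(h2$pos_counts[100], 1L)

  expect_error(build_histogram(calib[0, ]), "empty")
  expect_error(build_histogram(calib, bin_width = 0.03), "integer number")
})

test_that("posterior smoothing implements raw, add-one and isotonic rules", {
  calib <- make_calibration(rep(0.955, 9), c(0.955, rep(0.045, 9), 0.5))
  h <- build_histogram(calib, bin_width = 0.01)
  raw <- estimate_posteriors(h, "none")
  expect_equal(raw$posterior[96], 0.9)        # pos 9, neg 1
  expect_true(is.na(raw$posterior[50]))       # empty bin undefined
  a1 <- estimate_posteriors(h, "add_one")
  expect_equal(a1$posterior[96], 10 / 12)
  expect_equal(a1$posterior[50], 0.5)         # empty bin shrinks to 1/2
  iso <- estimate_posteriors(h, "add_one_isotonic")
  expect_false(is.unsorted(iso$posterior))
  expect_true(all(iso$posterior >= 0 & iso$posterior <= 1))
})

test_that("pool-adjacent-violators merges violating bins by weighted mean", {
  pava <- driverburden:::pava_nondecreasing
  expect_equal(pava(c(0.2, 0.8, 0.5), w = c(1, 1, 1)), c(0.2, 0.65, 0.65))
  expect_equal(pava(c(0.5, 0.4, 0.3), w = c(1, 1, 2)), rep(0.375, 3))
  expect_equal(pava(c(1, 2, 3, 4), w = rep(1, 4)),
               c(1, 2, 3, 4))  # already monotone: unchanged
  # equal weights agree with stats::isoreg
  set.seed(8)
  y <- runif(50)
  expect_equal(pava(y, rep(1, 50)), isoreg(y)$yf)
})

test_that("isotonic posteriors recover the analytic posterior on dense data", {
  m <- class_score_model(8, 2, 2, 8)
  calib <- simulate_calibration_set(m, 1e6, seed = 17)
  h <- estimate_posteriors(build_histogram(calib, 0.01), "add_one_isotonic")
  edges <- h$bin_edges
  f_pos <- diff(pbeta(edges, 8, 2))
  f_neg <- diff(pbeta(edges, 2, 8))
  analytic <- f_pos / (f_pos + f_neg)
  heavy <- (f_pos + f_neg) / 2 >= 1e-3
  expect_true(all(abs(h$posterior[heavy] - analytic[heavy]) < 0.05))
})

test_that("the FDR curve counts tails exactly", {
  calib <- make_calibration(c(0.9, 0.8, 0.6), c(0.1, 0.2, 0.7))
  fc <- fdr_curve(calib, thresholds = c(0, 0.5, 0.75))
  expect_equal(fc$tp, c(3L, 3L, 2L))
  expect_equal(fc$fp, c(3L, 1L, 0L))
  expect_equal(fc$fdr, c(0.5, 0.25, 0))
  expect_error(fdr_curve(calib, numeric(0)), "empty")
  # threshold 0 on any balanced set gives fdr 0.5
  set.seed(1)
  fc2 <- fdr_curve(make_calibration(runif(40), runif(40)),
                   thresholds = c(0, 0.5))
  expect_equal(fc2$fdr[1], 0.5)
  # imbalance is rejected
  expect_error(fdr_curve(make_calibration(runif(40), runif(10))),
               "imbalanced")
})

test_that("tp and fp are non-increasing in the threshold on random sets", {
  set.seed(99)
  for (i in 1:10) {
    n <- sample(10:100, 1)
    calib <- make_calibration(runif(n), runif(n))
    fc <- fdr_curve(calib)
    expect_true(all(diff(fc$tp) <= 0))
    expect_true(all(diff(fc$fp) <= 0))
  }
})

test_that("threshold selection applies the sustained-control rule", {
  calib <- make_calibration(c(0.9, 0.8, 0.6), c(0.1, 0.2, 0.7))
  fc <- fdr_curve(calib, thresholds = c(0, 0.5, 0.75))
  expect_equal(select_threshold(fc, 0.05), 0.75)
  # all fdr values below target: rule degenerates to the smallest threshold
  fc2 <- fdr_curve(make_calibration(c(0.8, 0.9), c(0.1, 0.2)),
                   thresholds = c(0.3, 0.5))
  expect_equal(select_threshold(fc2, 0.05), 0.3)
  # identically distributed classes: fdr ~ 0.5 everywhere, unachievable
  set.seed(4)
  same <- make_calibration(runif(5000), runif(5000))
  fc3 <- fdr_curve(same, thresholds = seq(0, 0.9, 0.1))
  expect_warning(t0 <- select_threshold(fc3, 0.05), "no grid threshold")
  expect_true(is.na(t0))
  # a non-monotone dip below target at an interior threshold is not selected
  # when a later threshold violates the target again
  curve <- structure(
    tibble::tibble(threshold = c(0.2, 0.4, 0.6, 0.8),
                   tp = c(40L, 30L, 20L, 10L), fp = c(10L, 1L, 5L, 0L),
                   fdr = c(0.2, 1 / 31, 0.2, 0)),
    class = c("fdr_curve", class(tibble::tibble())))
  expect_equal(select_threshold(curve, 0.05), 0.8)
})

test_that("the realized FDR at the selected threshold is controlled", {
  m <- class_score_model(8, 2, 2, 8)
  calib <- simulate_calibration_set(m, 50000, seed = 23)
  fc <- fdr_curve(calib)
  t0 <- select_threshold(fc, 0.05)
  expect_false(is.na(t0))
  fresh <- simulate_calibration_set(m, 50000, seed = 24)
  tp <- sum(fresh$p_score >= t0 & fresh$label == "driver")
  fp <- sum(fresh$p_score >= t0 & fresh$label == "neutral")
  expect_lte(fp / (tp + fp), 0.05 + 0.01)
})

test_that("the gene-reference line search recovers the generating threshold", {
  set.seed(55)
  genes <- sprintf("G%02d", 1:10)
  cohort <- make_records(rbeta(3000, 2, 2), sample_id = "S1",
                         gene = sample(genes, 3000, replace = TRUE))
  ref_counts <- table(factor(cohort$gene[cohort$p_score >= 0.7],
                             levels = genes))
  reference <- setNames(as.numeric(ref_counts), genes)
  grid <- seq(0, 1, by = 0.01)
  expect_equal(fit_threshold_to_gene_reference(cohort, reference, grid,
                                               "absolute"), 0.7)
  expect_equal(fit_threshold_to_gene_reference(cohort, reference, grid,
                                               "squared"), 0.7)
  # all-zero reference: largest threshold nulling every count (tie -> larger)
  zero_ref <- setNames(rep(0, 10), genes)
  expect_equal(fit_threshold_to_gene_reference(cohort, zero_ref, grid), 1)
  expect_error(fit_threshold_to_gene_reference(cohort, numeric(0)), "empty")
  no_genes <- make_records(runif(10))
  expect_error(fit_threshold_to_gene_reference(no_genes, reference),
               "no gene annotations")
})
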