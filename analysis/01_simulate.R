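#!/usr/bin/env Rscript
# Step 1: generate the synthetic study cohort and its calibration set.
#
# The cohort emulates a multi-type primary-tumour collection: seven cancer
# types spanning very low (THCA-like) to high (BLCA-like) driver burden, a
# bimodal type (COCA-like), stage-dependent accumulation (PRAD-like), a 1%
# hypermutant fraction (SKCM-like) and planted high-incidence driver genes
# (KRAS-like at 86.5% in the pancreatic-like type). Driver and passenger
# p-scores follow Beta(8, 2) and Beta(2, 8).
#
# Full per-variant tables go to scratch/ (large, regenerable); the ground
# truth per-type summary - what later steps try to recover - goes to
# results/. Downstream steps regenerate the cohort deterministically from
# the same seed rather than re-reading scratch/.

suppressPackageStartupMessages(library(driverburden))

seed <- 20260919L
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

score_model <- class_score_model(a_pos = 8, b_pos = 2, a_neg = 2, b_neg = 8)
calib <- simulate_calibration_set(score_model, n_per_class = 50000L,
                                  seed = seed)
sim <- simulate_cohort(default_cohort_model(), score_model, seed = seed + 1L)

cat(sprintf("calibration set: %d labelled scores (50:50 driver/neutral)\n",
            nrow(calib)))
cat(sprintf("cohort: %d variants across %d samples in %d cancer types\n",
            nrow(sim$records), nrow(sim$truth$samples),
            length(unique(sim$records$cancer_type))))
cat(sprintf("hypermutant samples planted: %d\n",
            sum(sim$truth$samples$hypermutant)))

readr::write_tsv(calib, "scratch/calibration.tsv")
write_predictions(sim$records, "scratch/cohort.tsv",
                  comments = sprintf("synthetic cohort, seed %d", seed + 1L))

write_summary(sim$truth$type_summary, "results/01_true_type_summary.tsv",
              comments = c("ground-truth per-type driver burden",
                           "(non-hypermutant samples)"))
cat("\nground truth per type (the target of the estimators):\n")
print.data.frame(as.data.frame(sim$truth$type_summary), digits = 3)
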