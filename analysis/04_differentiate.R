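#!/usr/bin/env Rscript
# Step 4: threshold-independence checks and cohort differentiation.
#
# Sweeps the p-score threshold over a grid, recomputing per-type medians
# (the relative ranking of types should be preserved across thresholds),
# and tests each type's driver-count distribution against the pooled rest
# with a two-sided Mann-Whitney U test.

suppressPackageStartupMessages(library(driverburden))

seed <- 20260919L
dir.create("results", showWarnings = FALSE)

score_model <- class_score_model(a_pos = 8, b_pos = 2, a_neg = 2, b_neg = 8)
calib <- simulate_calibration_set(score_model, n_per_class = 50000L,
                                  seed = seed)
t0 <- select_threshold(fdr_curve(calib), target_fdr = 0.05)
sim <- simulate_cohort(default_cohort_model(), score_model, seed = seed + 1L)

grid <- seq(0.3, 0.95, by = 0.05)
sweep <- sweep_thresholds(sim$records, grid)
write_summary(sweep, "results/04_threshold_sweep.tsv",
              comments = "per-type median/mean of thresholded counts by threshold")

# ranking preservation: rank correlation of type medians across thresholds
by_t <- split(sweep, sweep$threshold)
ranks <- sapply(by_t, function(d) rank(d$median[order(d$cancer_type)]))
rho <- cor(ranks[, 1], ranks[, ncol(ranks)], method = "spearman")
cat(sprintf(
  "Spearman correlation of type ranking, threshold %.2f vs %.2f: %.3f\n",
  grid[1], grid[length(grid)], rho))
cat("(ranking decays at the top of the grid where medians collapse toward\n")
cat(" 0 and tie; over the mid-range the type ordering is stable)\n")
rho_mid <- cor(ranks[, 1], ranks[, which(grid == 0.7)], method = "spearman")
cat(sprintf("Spearman correlation, threshold %.2f vs 0.70: %.3f\n",
            grid[1], rho_mid))

counts <- driver_counts(sim$records, threshold = t0,
                        samples = sim$truth$samples)
retained <- apply_hypermutation_filter(counts, 500L)$retained
mw <- dplyr::bind_rows(lapply(sort(unique(retained$cancer_type)),
                              function(ct) mann_whitney_vs_rest(retained, ct)))
write_summary(mw, "results/04_mannwhitney.tsv",
              comments = sprintf("two-sided Mann-Whitney vs pooled rest, threshold %.2f", t0))

cat("\nMann-Whitney differentiation (each type vs pooled rest):\n")
print.data.frame(as.data.frame(mw), digits = 3)
decisive <- mw$cancer_type[mw$p_value < 1e-10]
cat(sprintf("\n%d of %d types differ from the pooled rest at p < 1e-10: %s\n",
            length(decisive), nrow(mw), paste(decisive, collapse = ", ")))
cat(sprintf("most extreme: %s (p = %.2e); types whose burden sits near the\n",
            mw$cancer_type[which.min(mw$p_value)], min(mw$p_value)))
cat("cross-cohort centre are, as expected, not strongly differentiated.\n")
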