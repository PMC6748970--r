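# Shared fixtures: small record tables and score models built in code.

make_records <- function(p_score, sample_id = "S1", cancer_type = "THCA",
                         stage = NA_character_, gene = NA_character_,
                         region = "coding") {
  n <- length(p_score)
  tibble::tibble(
    chrom = rep("1", n),
    pos = seq_len(n),
    ref = rep("A", n),
    alt = rep("T", n),
    p_score = p_score,
    region = region,
    sample_id = rep_len(sample_id, n),
    cancer_type = rep_len(cancer_type, n),
    stage = rep_len(stage, n),
    gene = rep_len(gene, n)
  )
}

# Perfect-separation score model: drivers at 1, neutrals at 0.
point_mass_model <- function(driver = 1, neutral = 0) {
  class_score_model(point_mass_driver = driver, point_mass_neutral = neutral)
}

# Histogram with posteriors pinned to given values (white-box fixture for
# the weighted counting rule, whose contract is conditional on posteriors).
hist_with_posteriors <- function(posterior, bin_width = 1 / length(posterior),
                                 region = "coding") {
  n_bins <- length(posterior)
  structure(
    list(
      bin_width = bin_width,
      bin_edges = seq(0, 1, length.out = n_bins + 1L),
      pos_counts = rep(1L, n_bins),
      neg_counts = rep(1L, n_bins),
      posterior = posterior,
      smoothing = "add_one",
      region = region
    ),
    class = "score_histogram"
  )
}

# Labelled score tibble from raw vectors.
make_calibration <- function(driver_scores, neutral_scores,
                             region = "coding") {
  tibble::tibble(
    p_score = c(driver_scores, neutral_scores),
    label = rep(c("driver", "neutral"),
                c(length(driver_scores), length(neutral_scores))),
    region = region
  )
}

# Naive double-loop recount of tp/fp/fdr over a grid (oracle for fdr_curve).
fdr_recount <- function(calibration, thresholds) {
  tp <- integer(length(thresholds))
  fp <- integer(length(thresholds))
  for (i in seq_along(thresholds)) {
    for (j in seq_len(nrow(calibration))) {
      if (calibration$p_score[j] >= thresholds[i]) {
        if (calibration$label[j] == "driver") tp[i] <- tp[i] + 1L
        else fp[i] <- fp[i] + 1L
      }
    }
  }
  fdr <- ifelse(tp + fp > 0, fp / (tp + fp), NA_real_)
  list(tp = tp, fp = fp, fdr = fdr)
}

# Brute-force two-sided Mann-Whitney p-value: enumerate every assignment of
# the pooled values into groups of size n_x, count U by pairwise comparison.
mw_permutation_oracle <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_pairs <- function(a, b) {
    u <- 0
    for (ai in a) for (bj in b) {
      u <- u + (ai > bj) + 0.5 * (ai == bj)
    }
    u
  }
  m <- nx * length(y) / 2
  u_obs <- u_pairs(x, y)
  sel <- utils::combn(length(pooled), nx)
  u_all <- apply(sel, 2, function(s) u_pairs(pooled[s], pooled[-s]))
  mean(abs(u_all - m) >= abs(u_obs - m) - 1e-9)
}
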