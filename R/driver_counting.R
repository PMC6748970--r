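# Per-sample SNV-driver counts: the thresholded rule (count scores >= t at
# the FDR-selected threshold) and the threshold-independent weighted rule
# (sum of per-bin posterior margins over eligible variants), plus the
# hypermutation filter.

assert_single_sample <- function(records) {
  if (nrow(records) == 0L) return(invisible(TRUE))
  if (length(unique(records$sample_id)) > 1L) {
    stop("records span multiple samples; counting is per sample",
         call. = FALSE)
  }
  if (length(unique(records$region)) > 1L) {
    stop("records span multiple regions; counting is per region",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Thresholded driver count for one sample
#'
#' Counts the sample's variants with `p_score >= threshold` (ties at the
#' threshold are included, consistent with the "equal to or exceeding" gene
#' rule).
#'
#' @param records Prediction records of one sample and one region.
#' @param threshold Threshold in \[0, 1\].
#' @return Integer count.
#' @export
#'
#' @examples
#' r <- tibble::tibble(p_score = c(0.95, 0.90, 0.30),
#'                     sample_id = "S1", region = "coding")
#' count_thresholded(r, 0.88)  # 2
count_thresholded <- function(records, threshold) {
  if (threshold < 0 || threshold > 1) {
    stop("`threshold` must lie in [0, 1]", call. = FALSE)
  }
  assert_single_sample(records)
  sum(records$p_score >= threshold)
}

#' Per-record weighted contribution
#'
#' For each p-score, looks up its histogram bin's posterior `p_b` and returns
#' the contribution `2*p_b - 1` when the bin is eligible (`p_b > 0.5`,
#' strict), else 0. With `smoothing = "none"` a score landing in a bin with
#' no calibration mass is an error naming the bin.
#'
#' @param p_score Numeric vector of scores.
#' @param hist A `score_histogram` with posteriors estimated.
#' @return Numeric vector of contributions in \[0, 1\].
#' @export
weighted_contribution <- function(p_score, hist) {
  stopifnot(inherits(hist, "score_histogram"))
  if (is.null(hist$posterior)) {
    stop("histogram posteriors have not been estimated", call. = FALSE)
  }
  idx <- score_bin(p_score, hist$bin_width)
  post <- hist$posterior[idx]
  if (anyNA(post)) {
    bad <- idx[which(is.na(post))[1]]
    stop(sprintf(
      "p-score falls in bin %d [%.2f, %.2f) with undefined posterior (no calibration mass; smoothing = 'none')",
      bad, hist$bin_edges[bad], hist$bin_edges[bad + 1L]), call. = FALSE)
  }
  ifelse(post > 0.5, 2 * post - 1, 0)
}

#' Threshold-independent weighted driver count for one sample
#'
#' Each variant whose score falls in histogram bin `b` contributes
#' `(+1) p(driver | called driver, bin b) + (-1) p(neutral | called driver,
#' bin b) = 2*p_b - 1`, provided the bin is eligible (`p_b > 0.5`); the
#' weighted count is the sum of these contributions. This admits
#' low-confidence calls, down-weighted by the probability that they are
#' false positives, and equals the expected number of true-positive minus
#' false-positive driver calls among eligible variants.
#'
#' @param records Prediction records of one sample and one region matching
#'   `hist$region`.
#' @param hist A `score_histogram` with posteriors estimated.
#' @return Non-negative real count, at most `nrow(records)`.
#' @export
count_weighted <- function(records, hist) {
  assert_single_sample(records)
  if (nrow(records) > 0L && !is.na(hist$region) &&
      !all(records$region == hist$region)) {
    stop("record region does not match histogram region", call. = FALSE)
  }
  sum(weighted_contribution(records$p_score, hist))
}

#' Per-sample driver counts for a cohort
#'
#' Computes, for every sample in the cohort, the number of variants, the
#' thresholded driver count (when `threshold` is given), the weighted count
#' (when `hist` is given), and the hypermutant flag. The hypermutant flag is
#' based on the thresholded count when a threshold was applied (the filter
#' precedes all reported statistics in the pipeline order), otherwise on the
#' weighted count.
#'
#' @param cohort Prediction-record tibble (one region).
#' @param threshold Optional p-score threshold.
#' @param hist Optional `score_histogram` with posteriors (for weighted
#'   counts).
#' @param hypermutation_max Hypermutation cutoff; a sample is flagged when
#'   its applicable count is strictly greater. Default 500.
#' @param samples Optional tibble with columns `sample_id`, `cancer_type`,
#'   `stage` listing every sample of the cohort; samples with no record rows
#'   (zero variants) then appear with all counts 0 instead of being absent.
#' @return Tibble with columns `sample_id`, `cancer_type`, `stage`, `region`,
#'   `n_variants`, `count_thresholded`, `count_weighted`, `hypermutant`,
#'   `threshold_used`.
#' @export
driver_counts <- function(cohort, threshold = NULL, hist = NULL,
                          hypermutation_max = 500L, samples = NULL) {
  if (is.null(threshold) && is.null(hist)) {
    stop("supply `threshold`, `hist`, or both", call. = FALSE)
  }
  if (length(unique(cohort$region)) > 1L) {
    stop("cohort spans multiple regions; count each region separately",
         call. = FALSE)
  }
  if (!is.null(hist) && nrow(cohort) > 0L && !is.na(hist$region) &&
      !all(cohort$region == hist$region)) {
    stop("cohort region does not match histogram region", call. = FALSE)
  }
  contrib <- if (!is.null(hist)) {
    weighted_contribution(cohort$p_score, hist)
  } else {
    rep(NA_real_, nrow(cohort))
  }
  hit <- if (!is.null(threshold)) {
    if (threshold < 0 || threshold > 1) {
      stop("`threshold` must lie in [0, 1]", call. = FALSE)
    }
    as.integer(cohort$p_score >= threshold)
  } else {
    rep(NA_integer_, nrow(cohort))
  }
  counts <- tibble::tibble(
    sample_id = cohort$sample_id, cancer_type = cohort$cancer_type,
    stage = cohort$stage, region = cohort$region,
    hit = hit, contrib = contrib
  ) |>
    dplyr::group_by(.data$sample_id, .data$cancer_type, .data$stage,
                    .data$region) |>
    dplyr::summarise(
      n_variants = dplyr::n(),
      count_thresholded = if (is.null(threshold)) NA_integer_ else
        as.integer(sum(.data$hit)),
      count_weighted = if (is.null(hist)) NA_real_ else sum(.data$contrib),
      .groups = "drop"
    )
  if (!is.null(samples)) {
    missing <- samples[!samples$sample_id %in% counts$sample_id, ,
                       drop = FALSE]
    if (nrow(missing) > 0L) {
      zero <- tibble::tibble(
        sample_id = missing$sample_id, cancer_type = missing$cancer_type,
        stage = missing$stage,
        region = if (nrow(cohort) > 0L) cohort$region[1] else NA_character_,
        n_variants = 0L,
        count_thresholded = if (is.null(threshold)) NA_integer_ else 0L,
        count_weighted = if (is.null(hist)) NA_real_ else 0
      )
      counts <- dplyr::bind_rows(counts, zero)
    }
  }
  applicable <- if (!is.null(threshold)) counts$count_thresholded else
    counts$count_weighted
  counts$hypermutant <- applicable > hypermutation_max
  counts$threshold_used <- if (is.null(threshold)) NA_real_ else threshold
  counts[order(counts$sample_id), ]
}

#' Partition samples by the hypermutation filter
#'
#' Samples whose applicable driver count strictly exceeds
#' `hypermutation_max` (default 500) are excluded from cohort statistics; a
#' sample with exactly `hypermutation_max` drivers is retained ("more than"
#' is strict). The applicable count is the thresholded one when a threshold
#' was applied, otherwise the weighted one; `count_kind` overrides.
#'
#' @param counts Tibble from [driver_counts()].
#' @param hypermutation_max Cutoff. Default 500.
#' @param count_kind `NULL` (automatic), `"thresholded"` or `"weighted"`.
#' @return List with tibbles `retained` and `excluded` (hypermutant flags
#'   updated to match the cutoff applied here).
#' @export
apply_hypermutation_filter <- function(counts, hypermutation_max = 500L,
                                       count_kind = NULL) {
  applicable <- if (is.null(count_kind)) {
    ifelse(is.na(counts$threshold_used), counts$count_weighted,
           as.numeric(counts$count_thresholded))
  } else {
    switch(match.arg(count_kind, c("thresholded", "weighted")),
           thresholded = as.numeric(counts$count_thresholded),
           weighted = counts$count_weighted)
  }
  if (anyNA(applicable)) {
    stop("applicable count is undefined for some samples", call. = FALSE)
  }
  excluded <- applicable > hypermutation_max
  counts$hypermutant <- excluded
  if (any(excluded)) {
    message(sprintf("hypermutation filter: excluded %d of %d samples (> %d drivers)",
                    sum(excluded), nrow(counts), hypermutation_max))
  }
  list(retained = counts[!excluded, , drop = FALSE],
       excluded = counts[excluded, , drop = FALSE])
}
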