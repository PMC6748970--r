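# Cohort summaries of per-sample driver counts: per-type mode/median/mean/
# quartiles, threshold sweeps, Mann-Whitney differentiation of one type
# against the pooled rest, and stratification by clinical stage.

# linear-interpolation quantile (order statistic at 1 + (n-1)*p), R type 7
quartiles <- function(x) {
  quantile(x, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
}

# Primary mode of integer counts: most frequent value, ties to smallest.
mode_integer <- function(x) {
  tab <- table(x)
  vals <- as.numeric(names(tab))
  min(vals[tab == max(tab)])
}

# Primary mode of real counts: midpoint of the most populated histogram bin
# of width w anchored at 0; ties to the leftmost bin.
mode_binned <- function(x, w) {
  idx <- floor(x / w + 1e-9)
  tab <- table(idx)
  bins <- as.numeric(names(tab))
  left <- min(bins[tab == max(tab)])
  (left + 0.5) * w
}

count_column <- function(counts, count_kind) {
  col <- switch(count_kind, thresholded = "count_thresholded",
                weighted = "count_weighted")
  x <- counts[[col]]
  if (anyNA(x)) {
    stop(sprintf("%s counts are undefined for some samples", count_kind),
         call. = FALSE)
  }
  as.numeric(x)
}

#' Summarise per-sample driver counts by cancer type
#'
#' For each cancer type computes the number of samples, the primary mode
#' (highest histogram peak: most frequent integer for thresholded counts
#' with ties to the smallest; for weighted counts the midpoint of the most
#' populated bin of width `mode_bin_width` anchored at 0, ties leftmost),
#' the median, the mean, and the quartiles (linear-interpolation rule,
#' order statistic at `1 + (n-1)p`). Apply the hypermutation filter first:
#' the summary describes the retained samples it is given.
#'
#' @param counts Tibble from [driver_counts()] (typically the `retained`
#'   part of [apply_hypermutation_filter()]).
#' @param count_kind `"thresholded"` (default) or `"weighted"`.
#' @param mode_bin_width Bin width for the mode of weighted counts.
#'   Default 1.
#' @return Tibble with columns `cancer_type`, `n_samples`, `mode`, `median`,
#'   `mean`, `q1`, `q3`, `count_kind`.
#' @export
#'
#' @examples
#' counts <- tibble::tibble(
#'   sample_id = paste0("S", 1:5), cancer_type = "THCA", stage = NA,
#'   region = "coding", n_variants = 20L,
#'   count_thresholded = c(0L, 1L, 1L, 2L, 10L),
#'   count_weighted = NA_real_, hypermutant = FALSE, threshold_used = 0.88
#' )
#' summarize_cohort(counts)  # mode 1, median 1, mean 2.8
summarize_cohort <- function(counts, count_kind = c("thresholded", "weighted"),
                             mode_bin_width = 1) {
  count_kind <- match.arg(count_kind)
  if (nrow(counts) == 0L) stop("no samples to summarise", call. = FALSE)
  x <- count_column(counts, count_kind)
  df <- tibble::tibble(cancer_type = counts$cancer_type, x = x)
  df |>
    dplyr::group_by(.data$cancer_type) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      mode = if (count_kind == "thresholded") mode_integer(.data$x) else
        mode_binned(.data$x, mode_bin_width),
      median = quartiles(.data$x)[2],
      mean = mean(.data$x),
      q1 = quartiles(.data$x)[1],
      q3 = quartiles(.data$x)[3],
      .groups = "drop"
    ) |>
    dplyr::mutate(count_kind = count_kind)
}

#' Sweep thresholded counts over a grid of p-score thresholds
#'
#' Recomputes the per-sample thresholded count and the hypermutation filter
#' at every grid threshold (hypermutant status depends on the threshold, so
#' the filter is re-applied each time), then the per-type median and mean
#' over the retained samples.
#'
#' @param cohort Prediction-record tibble (one region).
#' @param grid Non-empty ascending threshold grid.
#' @param hypermutation_max Hypermutation cutoff. Default 500.
#' @return Tibble with columns `threshold`, `cancer_type`, `n_retained`,
#'   `median`, `mean`.
#' @export
sweep_thresholds <- function(cohort, grid, hypermutation_max = 500L) {
  if (length(grid) == 0L) stop("threshold grid is empty", call. = FALSE)
  per_t <- lapply(grid, function(t) {
    counts <- driver_counts(cohort, threshold = t,
                            hypermutation_max = hypermutation_max)
    kept <- suppressMessages(
      apply_hypermutation_filter(counts, hypermutation_max))$retained
    kept |>
      dplyr::group_by(.data$cancer_type) |>
      dplyr::summarise(
        n_retained = dplyr::n(),
        median = median(.data$count_thresholded),
        mean = mean(.data$count_thresholded),
        .groups = "drop"
      ) |>
      dplyr::mutate(threshold = t, .before = 1)
  })
  dplyr::bind_rows(per_t)
}

# U statistic of x vs y with midrank tie handling:
# U = #{(i,j): x_i > y_j} + 0.5 #{x_i = y_j} = R_x - n_x(n_x+1)/2.
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# Exact two-sided p-value by enumeration of all group assignments of the
# pooled values (handles ties); p = P(|U - m| >= |u_obs - m|) under the null
# that the assignment is exchangeable, where m = n_x n_y / 2.
mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  m <- nx * (n - nx) / 2
  offset <- nx * (nx + 1) / 2
  sel <- utils::combn(n, nx)
  u_all <- colSums(matrix(r[sel], nrow = nx)) - offset
  u_obs <- sum(r[seq_len(nx)]) - offset
  mean(abs(u_all - m) >= abs(u_obs - m) - 1e-9)
}

#' Mann-Whitney differentiation of one cancer type against the rest
#'
#' Two-sided Mann-Whitney U test of the selected type's per-sample driver
#' counts against the pooled counts of all other types, testing whether the
#' type's counts are representative of the cross-cancer distribution. With
#' `n_type + n_rest <= 12` the p-value is computed by exact enumeration of
#' all group assignments of the pooled values (valid under ties; identical
#' multisets give p = 1); otherwise the normal approximation with tie and
#' continuity correction is used (via [stats::wilcox.test()]).
#'
#' @param counts Tibble from [driver_counts()] after hypermutation
#'   filtering, covering all types.
#' @param cancer_type The type to test against the pooled rest.
#' @param count_kind `"thresholded"` (default) or `"weighted"`.
#' @return One-row tibble: `cancer_type`, `U`, `p_value`, `n_type`,
#'   `n_rest`, `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_vs_rest <- function(counts, cancer_type,
                                 count_kind = c("thresholded", "weighted")) {
  count_kind <- match.arg(count_kind)
  vals <- count_column(counts, count_kind)
  in_type <- counts$cancer_type == cancer_type
  if (!any(in_type)) {
    stop("no samples for cancer type ", cancer_type, call. = FALSE)
  }
  if (all(in_type)) {
    stop("rest pool is empty: cohort contains only ", cancer_type,
         call. = FALSE)
  }
  x <- vals[in_type]; y <- vals[!in_type]
  u <- u_statistic(x, y)
  if (length(x) + length(y) <= 12L) {
    p <- mw_exact_p(x, y)
    method <- "exact"
  } else {
    p <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                  correct = TRUE))$p.value
    method <- "normal_approx"
  }
  tibble::tibble(cancer_type = cancer_type, U = u, p_value = p,
                 n_type = length(x), n_rest = length(y), method = method)
}

#' Stratify driver counts by clinical stage
#'
#' Per cancer type and stage (I-IV, in order), tabulates the number of
#' samples, mean, and quartiles of the per-sample driver count, and flags
#' whether the stage medians are non-decreasing across the stages observed
#' for the type (`monotone_medians`). Samples with unknown stage are
#' excluded, with a tally reported; stages with no samples are omitted, not
#' zero-filled.
#'
#' @param counts Tibble from [driver_counts()] after hypermutation
#'   filtering.
#' @param count_kind `"thresholded"` (default) or `"weighted"`.
#' @return Tibble with columns `cancer_type`, `stage`, `n`, `mean`, `q1`,
#'   `median`, `q3`, `monotone_medians` (constant within type). Types with
#'   no staged samples are omitted with a warning.
#' @export
stratify_by_stage <- function(counts,
                              count_kind = c("thresholded", "weighted")) {
  count_kind <- match.arg(count_kind)
  vals <- count_column(counts, count_kind)
  staged <- !is.na(counts$stage)
  n_unknown <- sum(!staged)
  if (n_unknown > 0L) {
    message(sprintf("stage stratification: excluding %d samples with unknown stage",
                    n_unknown))
  }
  if (!any(staged)) {
    warning("no samples with known stage; returning empty stage summary",
            call. = FALSE)
    return(tibble::tibble(cancer_type = character(), stage = character(),
                          n = integer(), mean = numeric(), q1 = numeric(),
                          median = numeric(), q3 = numeric(),
                          monotone_medians = logical()))
  }
  dropped <- setdiff(unique(counts$cancer_type),
                     unique(counts$cancer_type[staged]))
  if (length(dropped) > 0L) {
    warning("types with no staged samples omitted: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  df <- tibble::tibble(
    cancer_type = counts$cancer_type[staged],
    stage = factor(counts$stage[staged], levels = VALID_STAGES),
    x = vals[staged]
  )
  out <- df |>
    dplyr::group_by(.data$cancer_type, .data$stage) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$x),
      q1 = quartiles(.data$x)[1],
      median = quartiles(.data$x)[2],
      q3 = quartiles(.data$x)[3],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cancer_type, .data$stage) |>
    dplyr::group_by(.data$cancer_type) |>
    dplyr::mutate(monotone_medians = !is.unsorted(.data$median)) |>
    dplyr::ungroup()
  out$stage <- as.character(out$stage)
  out
}
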