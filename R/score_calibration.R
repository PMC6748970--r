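# Score calibration: class-conditional histograms of the balanced labelled
# score set, per-bin posterior driver probabilities, the FDR-vs-threshold
# curve, threshold selection at a target FDR, and fitting a threshold to
# external per-gene reference counts.

#' Bin index of a p-score
#'
#' Half-open bins [k*w, (k+1)*w); a score of exactly 1 falls in the last bin.
#' A small tolerance absorbs floating-point representation of scores that lie
#' on a bin edge (e.g. 0.91 with w = 0.01 lands in the bin starting at 0.91).
#'
#' @param p_score Numeric vector in \[0, 1\].
#' @param bin_width Bin width dividing 1 into an integer number of bins.
#' @return Integer bin indices in `1..(1/bin_width)`.
#' @keywords internal
score_bin <- function(p_score, bin_width) {
  n_bins <- as.integer(round(1 / bin_width))
  idx <- floor(p_score / bin_width + 1e-9) + 1L
  pmin(pmax(idx, 1L), n_bins)
}

#' Build class-conditional score histograms from a calibration set
#'
#' Bins the driver-labelled and neutral-labelled calibration scores into
#' half-open bins `[k*w, (k+1)*w)` (the final bin closed at 1). Posteriors
#' are not estimated here; see [estimate_posteriors()].
#'
#' @param calibration Tibble of labelled scores (columns `p_score`, `label`,
#'   optionally `region`), e.g. from [read_labeled_scores()] or
#'   [simulate_calibration_set()].
#' @param bin_width Bin width; `1 / bin_width` must be an integer.
#'   Default 0.01 (100 bins).
#' @param region Region tag stored on the histogram; taken from the data when
#'   unique and omitted.
#' @return An object of class `score_histogram`: a list with `bin_width`,
#'   `bin_edges` (length bins + 1), integer vectors `pos_counts` and
#'   `neg_counts`, `posterior` (`NULL` until estimated), `smoothing`, and
#'   `region`.
#' @export
#'
#' @examples
#' calib <- tibble::tibble(
#'   p_score = c(0.905, 0.915, 0.905),
#'   label = c("driver", "driver", "neutral")
#' )
#' h <- build_histogram(calib, bin_width = 0.01)
#' h$pos_counts[91:92]  # one driver in [0.90, 0.91), one in [0.91, 0.92)
build_histogram <- function(calibration, bin_width = 0.01, region = NULL) {
  if (is.null(calibration) || nrow(calibration) == 0L) {
    stop("calibration set is empty", call. = FALSE)
  }
  n_bins <- 1 / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-8) {
    stop("`bin_width` must divide 1 into an integer number of bins",
         call. = FALSE)
  }
  n_bins <- as.integer(round(n_bins))
  if (is.null(region)) {
    region <- if ("region" %in% names(calibration)) {
      r <- unique(calibration$region)
      if (length(r) == 1L) r else NA_character_
    } else {
      NA_character_
    }
  }
  idx <- score_bin(calibration$p_score, bin_width)
  is_pos <- calibration$label == "driver"
  pos <- tabulate(idx[is_pos], nbins = n_bins)
  neg <- tabulate(idx[!is_pos], nbins = n_bins)
  structure(
    list(
      bin_width = bin_width,
      bin_edges = seq(0, 1, length.out = n_bins + 1L),
      pos_counts = as.integer(pos),
      neg_counts = as.integer(neg),
      posterior = NULL,
      smoothing = NULL,
      region = region
    ),
    class = "score_histogram"
  )
}

#' @export
print.score_histogram <- function(x, ...) {
  cat(sprintf(
    "Score histogram: %d bins of width %g, %d driver / %d neutral scores (region: %s)\n",
    length(x$pos_counts), x$bin_width, sum(x$pos_counts), sum(x$neg_counts),
    if (is.na(x$region)) "unspecified" else x$region))
  if (is.null(x$posterior)) {
    cat("Posteriors not yet estimated\n")
  } else {
    cat(sprintf("Posteriors estimated (smoothing: %s), %d bins eligible (posterior > 0.5)\n",
                x$smoothing, sum(!is.na(x$posterior) & x$posterior > 0.5)))
  }
  invisible(x)
}

# Weighted pool-adjacent-violators: least-squares isotonic (non-decreasing)
# fit of y with weights w. Returns the fitted vector.
pava_nondecreasing <- function(y, w) {
  n <- length(y)
  if (n == 0L) return(y)
  # blocks stored as running (value, weight, size)
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    val[k] <- y[i]; wt[k] <- w[i]; sz[k] <- 1L
    while (k > 1L && val[k - 1L] > val[k]) {
      tot <- wt[k - 1L] + wt[k]
      val[k - 1L] <- (val[k - 1L] * wt[k - 1L] + val[k] * wt[k]) / tot
      wt[k - 1L] <- tot
      sz[k - 1L] <- sz[k - 1L] + sz[k]
      k <- k - 1L
    }
  }
  rep(val[seq_len(k)], times = sz[seq_len(k)])
}

#' Estimate per-bin posterior driver probabilities
#'
#' For each score bin, estimates `p(driver | predicted driver, score in bin)`
#' from the class-conditional calibration counts. Because the calibration set
#' is 50:50 balanced, the raw per-bin proportion `pos / (pos + neg)` is the
#' posterior estimate. Smoothing options:
#' \describe{
#'   \item{`none`}{raw proportion; bins with no calibration mass are marked
#'     undefined (`NA`) and any later use of such a bin errors.}
#'   \item{`add_one`}{Laplace smoothing `(pos + 1) / (pos + neg + 2)`.}
#'   \item{`add_one_isotonic`}{(default) add-one followed by a weighted
#'     pool-adjacent-violators pass so the posterior is non-decreasing in
#'     score, as expected of Platt-scaled classifier output; bins are
#'     weighted by their smoothed totals `pos + neg + 2`.}
#' }
#'
#' @param hist A `score_histogram` from [build_histogram()].
#' @param smoothing `"add_one_isotonic"` (default), `"add_one"` or `"none"`.
#' @return The histogram with `posterior` filled in and `smoothing` recorded.
#' @export
estimate_posteriors <- function(hist,
                                smoothing = c("add_one_isotonic", "add_one",
                                              "none")) {
  smoothing <- match.arg(smoothing)
  stopifnot(inherits(hist, "score_histogram"))
  pos <- hist$pos_counts
  neg <- hist$neg_counts
  tot <- pos + neg
  if (smoothing == "none") {
    post <- ifelse(tot > 0L, pos / tot, NA_real_)
  } else {
    post <- (pos + 1) / (tot + 2)
    if (smoothing == "add_one_isotonic") {
      post <- pava_nondecreasing(post, w = tot + 2)
    }
  }
  hist$posterior <- post
  hist$smoothing <- smoothing
  hist
}

#' Compute the FDR-versus-threshold curve from a calibration set
#'
#' For each threshold `t` on the grid, counts the calibration drivers
#' (`tp`) and neutrals (`fp`) with score `>= t`, and estimates the false
#' discovery rate `fp / (tp + fp)`. Under 50:50 class balance these tail
#' counts are the proxy for true and false driver calls at that threshold.
#' The FDR is undefined (`NA`) where no example passes. Counts use the raw
#' labelled scores, not the binned histogram, so tail counts are exact.
#'
#' @param calibration Tibble of labelled scores (`p_score`, `label`).
#' @param thresholds Ascending threshold grid in \[0, 1\].
#'   Default `seq(0, 1, by = 0.01)`.
#' @param balance_tolerance,enforce_balance Class-balance check as in
#'   [read_labeled_scores()].
#' @return An object of class `fdr_curve`: a tibble with columns
#'   `threshold`, `tp`, `fp`, `fdr`.
#' @export
#'
#' @examples
#' calib <- tibble::tibble(
#'   p_score = c(0.9, 0.8, 0.6, 0.1, 0.2, 0.7),
#'   label = rep(c("driver", "neutral"), each = 3)
#' )
#' fdr_curve(calib, thresholds = c(0, 0.5, 0.75))
fdr_curve <- function(calibration, thresholds = seq(0, 1, by = 0.01),
                      balance_tolerance = 0.05, enforce_balance = TRUE) {
  if (length(thresholds) == 0L) {
    stop("threshold grid is empty", call. = FALSE)
  }
  if (any(diff(thresholds) <= 0)) {
    stop("threshold grid must be strictly increasing", call. = FALSE)
  }
  n_pos <- sum(calibration$label == "driver")
  n_neg <- sum(calibration$label == "neutral")
  imbalance <- abs(n_pos - n_neg) / max(1L, nrow(calibration))
  if (imbalance > balance_tolerance) {
    msg <- sprintf("calibration set is imbalanced (imbalance %.3f)", imbalance)
    if (enforce_balance) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  pos_scores <- sort(calibration$p_score[calibration$label == "driver"])
  neg_scores <- sort(calibration$p_score[calibration$label == "neutral"])
  # #{scores >= t} via binary search on the sorted vectors
  tp <- length(pos_scores) - findInterval(thresholds, pos_scores,
                                          left.open = TRUE)
  fp <- length(neg_scores) - findInterval(thresholds, neg_scores,
                                          left.open = TRUE)
  fdr <- ifelse(tp + fp > 0L, fp / (tp + fp), NA_real_)
  structure(
    tibble::tibble(threshold = thresholds, tp = as.integer(tp),
                   fp = as.integer(fp), fdr = fdr),
    class = c("fdr_curve", class(tibble::tibble())))
}

#' Select the p-score threshold controlling FDR at a target
#'
#' Returns the smallest grid threshold `t` such that the estimated FDR is at
#' or below `target_fdr` at `t` and at every larger grid threshold where the
#' FDR is defined (sustained-control rule). Empirical FDR curves need not be
#' monotone; requiring control at all larger thresholds is the conservative,
#' deterministic resolution. If no grid threshold achieves sustained control,
#' `NA` is returned with a warning.
#'
#' @param curve An `fdr_curve` from [fdr_curve()].
#' @param target_fdr Target FDR in (0, 1). Default 0.05.
#' @return The selected threshold, or `NA_real_` if unachievable.
#' @export
select_threshold <- function(curve, target_fdr = 0.05) {
  stopifnot(inherits(curve, "fdr_curve"))
  if (target_fdr <= 0 || target_fdr >= 1) {
    stop("`target_fdr` must be in (0, 1)", call. = FALSE)
  }
  violates <- !is.na(curve$fdr) & curve$fdr > target_fdr
  # suffix count of violations at thresholds >= t
  suffix <- rev(cumsum(rev(violates)))
  ok <- which(suffix == 0L)
  if (length(ok) == 0L) {
    warning(sprintf("no grid threshold achieves sustained FDR <= %g",
                    target_fdr), call. = FALSE)
    return(NA_real_)
  }
  curve$threshold[ok[1]]
}

#' Fit a p-score threshold to external per-gene reference counts
#'
#' When an external model supplies per-gene driver counts for the cohort, the
#' p-score cutoff can be chosen to make the thresholded per-gene counts
#' conform: a one-dimensional line search over the grid minimising the sum
#' over genes of the absolute (or squared) difference between
#' `#\{records in gene g with p_score >= t\}` and the reference count.
#' Genes in the reference absent from the cohort count as predicted 0.
#' Ties in the objective are broken toward the larger threshold.
#'
#' @param cohort Tibble of prediction records with `gene` populated.
#' @param reference Named numeric vector: reference driver count per gene.
#' @param grid Threshold grid to search. Default `seq(0, 1, by = 0.01)`.
#' @param loss `"absolute"` (default) or `"squared"`.
#' @return The grid threshold minimising the objective.
#' @export
fit_threshold_to_gene_reference <- function(cohort, reference,
                                            grid = seq(0, 1, by = 0.01),
                                            loss = c("absolute", "squared")) {
  loss <- match.arg(loss)
  if (length(reference) == 0L) {
    stop("per-gene reference is empty", call. = FALSE)
  }
  if (is.null(names(reference)) || any(!nzchar(names(reference)))) {
    stop("`reference` must be a named vector (gene -> count)", call. = FALSE)
  }
  ann <- cohort[!is.na(cohort$gene), , drop = FALSE]
  if (nrow(ann) == 0L) {
    stop("cohort has no gene annotations", call. = FALSE)
  }
  genes <- names(reference)
  loss_fn <- if (loss == "absolute") abs else function(d) d^2
  objective <- vapply(grid, function(t) {
    hit <- ann[ann$p_score >= t, , drop = FALSE]
    pred <- table(factor(hit$gene, levels = genes))
    sum(loss_fn(as.numeric(pred) - as.numeric(reference)))
  }, numeric(1))
  best <- max(which(objective == min(objective)))  # ties toward larger t
  grid[best]
}
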