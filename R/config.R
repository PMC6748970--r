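#' Analysis configuration
#'
#' Bundles the tunable parameters of the driver-burden pipeline with their
#' defaults: the target false discovery rate used to select a p-score
#' threshold, the score histogram bin width, the hypermutation cutoff, the
#' threshold grid, the bin width used when locating the mode of real-valued
#' weighted counts, and the posterior smoothing scheme.
#'
#' @param target_fdr Target false discovery rate in (0, 1). Default 0.05.
#' @param bin_width Score histogram bin width; must divide 1 into an integer
#'   number of bins. Default 0.01 (100 bins).
#' @param hypermutation_max Samples with strictly more than this many drivers
#'   are flagged hypermutant and excluded from cohort statistics. Default 500.
#' @param region `"coding"` or `"noncoding"`.
#' @param threshold_grid Strictly increasing grid of thresholds in \[0, 1\].
#'   Default `seq(0, 1, by = bin_width)`, the histogram bin edges.
#' @param mode_bin_width Histogram bin width used to locate the primary mode
#'   of real-valued (weighted) counts. Default 1.
#' @param smoothing Posterior smoothing: `"none"`, `"add_one"` or
#'   `"add_one_isotonic"` (default).
#' @param seed Integer seed recorded alongside the configuration.
#'
#' @return A list of class `analysis_config`.
#' @export
#'
#' @examples
#' cfg <- analysis_config(target_fdr = 0.05)
#' cfg$hypermutation_max
analysis_config <- function(target_fdr = 0.05,
                            bin_width = 0.01,
                            hypermutation_max = 500L,
                            region = c("coding", "noncoding"),
                            threshold_grid = NULL,
                            mode_bin_width = 1,
                            smoothing = c("add_one_isotonic", "add_one", "none"),
                            seed = 1L) {
  region <- match.arg(region)
  smoothing <- match.arg(smoothing)
  if (!is.numeric(target_fdr) || length(target_fdr) != 1L ||
      target_fdr <= 0 || target_fdr >= 1) {
    stop("`target_fdr` must be a single number in (0, 1)", call. = FALSE)
  }
  n_bins <- 1 / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-8) {
    stop("`bin_width` must divide 1 into an integer number of bins",
         call. = FALSE)
  }
  if (is.null(threshold_grid)) {
    threshold_grid <- seq(0, 1, by = bin_width)
  }
  if (any(diff(threshold_grid) <= 0)) {
    stop("`threshold_grid` must be strictly increasing", call. = FALSE)
  }
  if (any(threshold_grid < 0 | threshold_grid > 1)) {
    stop("`threshold_grid` values must lie in [0, 1]", call. = FALSE)
  }
  if (hypermutation_max < 0) {
    stop("`hypermutation_max` must be non-negative", call. = FALSE)
  }
  structure(
    list(
      target_fdr = target_fdr,
      bin_width = bin_width,
      hypermutation_max = as.integer(hypermutation_max),
      region = region,
      threshold_grid = threshold_grid,
      mode_bin_width = mode_bin_width,
      smoothing = smoothing,
      seed = as.integer(seed)
    ),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from a YAML file
#'
#' The file holds keys mirroring the [analysis_config()] argument names;
#' absent keys take the defaults. A `threshold_grid` may be given either as a
#' list of values or as a string `"lo:hi:step"`.
#'
#' @param path Path to a YAML file.
#' @return An `analysis_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0L) {
    warning("ignoring unknown config keys: ", paste(extra, collapse = ", "),
            call. = FALSE)
    raw <- raw[intersect(names(raw), known)]
  }
  if (is.character(raw$threshold_grid) && length(raw$threshold_grid) == 1L) {
    parts <- as.numeric(strsplit(raw$threshold_grid, ":", fixed = TRUE)[[1]])
    if (length(parts) != 3L || anyNA(parts)) {
      stop("threshold_grid string must be of the form 'lo:hi:step'",
           call. = FALSE)
    }
    raw$threshold_grid <- seq(parts[1], parts[2], by = parts[3])
  }
  if (!is.null(raw$threshold_grid)) {
    raw$threshold_grid <- as.numeric(unlist(raw$threshold_grid))
  }
  do.call(analysis_config, raw)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Driver-burden analysis configuration\n")
  cat(sprintf("  target FDR:        %g\n", x$target_fdr))
  cat(sprintf("  bin width:         %g (%d bins)\n", x$bin_width,
              as.integer(round(1 / x$bin_width))))
  cat(sprintf("  hypermutation max: %d drivers\n", x$hypermutation_max))
  cat(sprintf("  region:            %s\n", x$region))
  cat(sprintf("  threshold grid:    %d points in [%g, %g]\n",
              length(x$threshold_grid), min(x$threshold_grid),
              max(x$threshold_grid)))
  cat(sprintf("  smoothing:         %s\n", x$smoothing))
  invisible(x)
}
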