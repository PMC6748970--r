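# Gene incidence: per cancer type, the fraction of samples carrying at
# least one high-confidence SNV-driver in each gene, with ranking within a
# type and profiling of one gene across types.

#' Per-gene driver incidence within each cancer type
#'
#' For every (cancer type, gene) pair observed in the cohort, computes the
#' fraction of the type's samples carrying at least one variant in that gene
#' with `p_score >= threshold` (the "equal to or exceeding" rule). A sample
#' counts once per gene regardless of how many qualifying variants it
#' carries; the denominator is all samples of the type present in the
#' cohort, including samples with no qualifying variant anywhere. Exclude
#' hypermutant samples upstream (pass their ids in `exclude_samples`).
#'
#' @param cohort Prediction-record tibble with `gene` populated (rows with
#'   `NA` gene are ignored for the numerator but their samples still count
#'   in the denominator).
#' @param threshold p-score threshold, e.g. the FDR-selected one.
#' @param region Optional region filter applied before counting.
#' @param exclude_samples Optional character vector of sample ids to drop
#'   (e.g. hypermutants).
#' @return Tibble with columns `cancer_type`, `gene`, `n_samples`,
#'   `n_with_driver`, `incidence`, `threshold_used`, sorted by type then
#'   gene.
#' @export
gene_incidence <- function(cohort, threshold, region = NULL,
                           exclude_samples = NULL) {
  if (threshold < 0 || threshold > 1) {
    stop("`threshold` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(region)) {
    cohort <- cohort[cohort$region == region, , drop = FALSE]
  }
  if (!is.null(exclude_samples)) {
    cohort <- cohort[!cohort$sample_id %in% exclude_samples, , drop = FALSE]
  }
  if (all(is.na(cohort$gene))) {
    stop("cohort has no gene annotations", call. = FALSE)
  }
  denom <- cohort |>
    dplyr::distinct(.data$cancer_type, .data$sample_id) |>
    dplyr::count(.data$cancer_type, name = "n_samples")
  genes <- cohort |>
    dplyr::filter(!is.na(.data$gene)) |>
    dplyr::distinct(.data$cancer_type, .data$gene)
  hits <- cohort |>
    dplyr::filter(!is.na(.data$gene), .data$p_score >= threshold) |>
    dplyr::distinct(.data$cancer_type, .data$gene, .data$sample_id) |>
    dplyr::count(.data$cancer_type, .data$gene, name = "n_with_driver")
  genes |>
    dplyr::left_join(hits, by = c("cancer_type", "gene")) |>
    dplyr::left_join(denom, by = "cancer_type") |>
    dplyr::mutate(
      n_with_driver = dplyr::coalesce(.data$n_with_driver, 0L),
      incidence = .data$n_with_driver / .data$n_samples,
      threshold_used = threshold
    ) |>
    dplyr::select("cancer_type", "gene", "n_samples", "n_with_driver",
                  "incidence", "threshold_used") |>
    dplyr::arrange(.data$cancer_type, .data$gene)
}

#' Rank genes by driver incidence within one cancer type
#'
#' @param incidences Tibble from [gene_incidence()].
#' @param cancer_type Type to rank within; must be present.
#' @param top_k Number of genes to keep.
#' @return Tibble of the top `top_k` genes, descending by incidence, ties
#'   broken lexicographically by gene symbol.
#' @export
rank_genes <- function(incidences, cancer_type, top_k = 5L) {
  sub <- incidences[incidences$cancer_type == cancer_type, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("no incidences for cancer type ", cancer_type, call. = FALSE)
  }
  sub <- sub[order(-sub$incidence, sub$gene), , drop = FALSE]
  head(sub, top_k)
}

#' Profile one gene's driver incidence across cancer types
#'
#' @param incidences Tibble from [gene_incidence()] covering all types.
#' @param gene Gene symbol (exact string match).
#' @return Tibble with one row per cancer type present in `incidences`
#'   (ordered by type code), with incidence 0 where the gene was not
#'   observed in the type. An all-zero table is a valid result, not an
#'   error.
#' @export
gene_across_cancers <- function(incidences, gene) {
  types <- sort(unique(incidences$cancer_type))
  sub <- incidences[incidences$gene == gene, , drop = FALSE]
  out <- tibble::tibble(cancer_type = types, gene = gene)
  out <- dplyr::left_join(
    out, sub[, c("cancer_type", "n_samples", "n_with_driver", "incidence")],
    by = "cancer_type")
  denom <- incidences |>
    dplyr::distinct(.data$cancer_type, .data$n_samples)
  miss <- is.na(out$incidence)
  if (any(miss)) {
    out$n_samples[miss] <- denom$n_samples[match(out$cancer_type[miss],
                                                 denom$cancer_type)]
    out$n_with_driver[miss] <- 0L
    out$incidence[miss] <- 0
  }
  out
}
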