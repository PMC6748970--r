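# Synthetic calibration sets and tumour cohorts with known ground truth.
# Class-conditional p-scores are Beta-distributed (optionally point masses
# for exact-recovery scenarios); per-sample driver counts are Poisson or a
# two-component Poisson mixture (emulating multi-modal "neo-modal" cohorts),
# with optional stage-dependent accumulation, hypermutant outliers and
# planted high-incidence driver genes.

#' Class-conditional p-score model
#'
#' Parametric stand-in for the empirical class-conditional score
#' distributions of a driver/neutral classifier: driver scores drawn from
#' `Beta(a_pos, b_pos)` (skewed toward 1), neutral scores from
#' `Beta(a_neg, b_neg)` (skewed toward 0). Optional point-mass overrides pin
#' each class to a single score value, giving perfect-separation scenarios
#' with exactly recoverable counts.
#'
#' @param a_pos,b_pos Beta shape parameters for driver scores. Default (8, 2).
#' @param a_neg,b_neg Beta shape parameters for neutral scores. Default (2, 8).
#' @param point_mass_driver,point_mass_neutral Optional fixed score per class;
#'   when set, the Beta parameters for that class are ignored.
#' @return A list of class `class_score_model`.
#' @export
class_score_model <- function(a_pos = 8, b_pos = 2, a_neg = 2, b_neg = 8,
                              point_mass_driver = NULL,
                              point_mass_neutral = NULL) {
  if (any(c(a_pos, b_pos, a_neg, b_neg) <= 0)) {
    stop("Beta shape parameters must be positive", call. = FALSE)
  }
  for (pm in c(point_mass_driver, point_mass_neutral)) {
    if (pm < 0 || pm > 1) stop("point masses must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(a_pos = a_pos, b_pos = b_pos, a_neg = a_neg, b_neg = b_neg,
         point_mass_driver = point_mass_driver,
         point_mass_neutral = point_mass_neutral),
    class = "class_score_model"
  )
}

draw_scores <- function(model, n, class = c("driver", "neutral")) {
  class <- match.arg(class)
  if (n == 0L) return(numeric(0))
  if (class == "driver") {
    if (!is.null(model$point_mass_driver)) return(rep(model$point_mass_driver, n))
    rbeta(n, model$a_pos, model$b_pos)
  } else {
    if (!is.null(model$point_mass_neutral)) return(rep(model$point_mass_neutral, n))
    rbeta(n, model$a_neg, model$b_neg)
  }
}

# P(score in bin b) per class, for each half-open bin defined by edges.
class_bin_probs <- function(model, bin_edges, class = c("driver", "neutral")) {
  class <- match.arg(class)
  n_bins <- length(bin_edges) - 1L
  pm <- if (class == "driver") model$point_mass_driver else model$point_mass_neutral
  if (!is.null(pm)) {
    probs <- numeric(n_bins)
    idx <- score_bin(pm, bin_edges[2] - bin_edges[1])
    probs[idx] <- 1
    return(probs)
  }
  if (class == "driver") {
    diff(pbeta(bin_edges, model$a_pos, model$b_pos))
  } else {
    diff(pbeta(bin_edges, model$a_neg, model$b_neg))
  }
}

#' Simulate a balanced labelled calibration set
#'
#' Draws exactly `n_per_class` driver-labelled and `n_per_class`
#' neutral-labelled p-scores from the class score model, emulating the 50:50
#' balanced labelled test output used for calibration.
#'
#' @param model A [class_score_model()].
#' @param n_per_class Examples per class (>= 1).
#' @param seed Integer seed; identical `(model, n_per_class, seed)` give
#'   identical output.
#' @param region Region tag stored on every row. Default `"coding"`.
#' @return Tibble with columns `p_score`, `label`, `region`.
#' @export
simulate_calibration_set <- function(model, n_per_class, seed = 1L,
                                     region = "coding") {
  if (!is.numeric(n_per_class) || n_per_class < 1) {
    stop("`n_per_class` must be a positive integer", call. = FALSE)
  }
  n_per_class <- as.integer(n_per_class)
  set.seed(seed)
  tibble::tibble(
    p_score = c(draw_scores(model, n_per_class, "driver"),
                draw_scores(model, n_per_class, "neutral")),
    label = rep(c("driver", "neutral"), each = n_per_class),
    region = region
  )
}

#' Specification of one synthetic cancer-type cohort
#'
#' Describes the generative model for one cancer type: the number of
#' samples, the per-sample true driver count distribution (Poisson, or a
#' two-component Poisson mixture emulating multi-modal cohorts), the
#' passenger count distribution, stage mixing and stage-dependent driver
#' accumulation, hypermutant outliers, and the gene placement model.
#'
#' @param cancer_type Short type code, e.g. `"THCA"`.
#' @param n_samples Number of tumour samples.
#' @param driver_lambda Poisson mean of the per-sample true driver count
#'   (first mixture component).
#' @param driver_lambda2,mixture_weight Optional second Poisson component
#'   and its weight: with probability `mixture_weight` a sample's drivers
#'   are drawn at `driver_lambda2`.
#' @param passenger_mu Poisson mean of the per-sample passenger count.
#' @param stage_probs Named marginal probabilities over stages
#'   `I`..`IV` (and optionally `unknown`); must sum to 1. Stage is assigned
#'   independently per sample. Default: uniform over I-IV.
#' @param stage_multipliers Named multipliers on `driver_lambda` per stage
#'   (all 1 = stage-constant accumulation). Default all 1.
#' @param hypermutant_fraction Fraction of samples drawn as hypermutant, with
#'   driver counts `501 + Poisson(hypermutant_lambda)` (always above the
#'   default 500-driver cutoff).
#' @param hypermutant_lambda Poisson mean of the hypermutant excess.
#'   Default 200.
#' @param driver_gene_weights Named selection weights: each driver variant is
#'   placed in a gene drawn proportionally to these. Default: uniform over
#'   `passenger_genes`.
#' @param planted_gene_incidence Named per-sample probabilities that a sample
#'   carries at least one driver in the given gene; planted drivers are
#'   added on top of the background driver count, so a gene planted at 0.865
#'   has binomial incidence 0.865 regardless of the count distribution.
#' @param passenger_genes Gene symbols over which passengers are placed
#'   uniformly. Default `"G001".."G100"`.
#' @return A list of class `cancer_type_spec`.
#' @export
cancer_type_spec <- function(cancer_type, n_samples,
                             driver_lambda,
                             driver_lambda2 = NULL, mixture_weight = NULL,
                             passenger_mu = 30,
                             stage_probs = c(I = 0.25, II = 0.25,
                                             III = 0.25, IV = 0.25),
                             stage_multipliers = c(I = 1, II = 1,
                                                   III = 1, IV = 1),
                             hypermutant_fraction = 0,
                             hypermutant_lambda = 200,
                             driver_gene_weights = NULL,
                             planted_gene_incidence = NULL,
                             passenger_genes = sprintf("G%03d", 1:100)) {
  if (driver_lambda < 0 || passenger_mu < 0) {
    stop("count rates must be non-negative", call. = FALSE)
  }
  if (!is.null(mixture_weight) &&
      (mixture_weight < 0 || mixture_weight > 1)) {
    stop("`mixture_weight` must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(stage_probs) - 1) > 1e-8) {
    stop("`stage_probs` must sum to 1", call. = FALSE)
  }
  if (hypermutant_fraction < 0 || hypermutant_fraction >= 1) {
    stop("`hypermutant_fraction` must lie in [0, 1)", call. = FALSE)
  }
  if (length(passenger_genes) == 0L && passenger_mu > 0) {
    stop("passenger gene pool is empty but passenger_mu > 0", call. = FALSE)
  }
  if (is.null(driver_gene_weights)) {
    if (length(passenger_genes) == 0L && driver_lambda > 0) {
      stop("no gene pool available for placing drivers", call. = FALSE)
    }
    driver_gene_weights <- setNames(rep(1, length(passenger_genes)),
                                    passenger_genes)
  }
  structure(
    list(cancer_type = cancer_type, n_samples = as.integer(n_samples),
         driver_lambda = driver_lambda, driver_lambda2 = driver_lambda2,
         mixture_weight = mixture_weight, passenger_mu = passenger_mu,
         stage_probs = stage_probs, stage_multipliers = stage_multipliers,
         hypermutant_fraction = hypermutant_fraction,
         hypermutant_lambda = hypermutant_lambda,
         driver_gene_weights = driver_gene_weights,
         planted_gene_incidence = planted_gene_incidence,
         passenger_genes = passenger_genes),
    class = "cancer_type_spec"
  )
}

#' Multi-type synthetic cohort model
#'
#' @param ... [cancer_type_spec()] objects, one per cancer type.
#' @return A list of class `cohort_model`.
#' @export
cohort_model <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1]]) &&
      !inherits(specs[[1]], "cancer_type_spec")) {
    specs <- specs[[1]]
  }
  ok <- vapply(specs, inherits, logical(1), "cancer_type_spec")
  if (length(specs) == 0L || !all(ok)) {
    stop("`cohort_model()` takes one or more cancer_type_spec objects",
         call. = FALSE)
  }
  names(specs) <- vapply(specs, `[[`, character(1), "cancer_type")
  structure(specs, class = "cohort_model")
}

#' Default synthetic cohort: the study conditions
#'
#' A cohort emulating the qualitative structure reported for primary solid
#' tumours: a large thyroid-like type (THCA, 528 samples) with very low
#' driver burden and a dominant BRAF-like driver gene; a breast-like type
#' (BRCA) with a mean of about 6 coding drivers; a bladder-like type (BLCA)
#' with the highest burden; a pancreatic-like type (PACA) with planted
#' KRAS-like (incidence 0.865) and TP53-like (0.410) driver genes; a
#' colorectal-like type (COCA) with a bimodal driver-count mixture and
#' stage-increasing burden; a melanoma-like type (SKCM) with heavy passenger
#' load and a 1\% hypermutant fraction; and a prostate-like type (PRAD) with
#' monotone stage accumulation.
#'
#' @param scale Multiplier on all per-type sample sizes (default 1).
#' @return A `cohort_model`.
#' @export
default_cohort_model <- function(scale = 1) {
  pool <- sprintf("G%03d", 1:100)
  zipf <- function(genes) setNames(1 / seq_along(genes), genes)
  n <- function(k) max(2L, as.integer(round(k * scale)))
  cohort_model(
    cancer_type_spec("THCA", n(528), driver_lambda = 0.8, passenger_mu = 25,
                     planted_gene_incidence = c(BRAF = 0.558),
                     driver_gene_weights = zipf(c("NRAS", "TTN", pool))),
    cancer_type_spec("BRCA", n(400), driver_lambda = 6, passenger_mu = 35,
                     driver_gene_weights = zipf(c("TP53", "PIK3CA", pool))),
    cancer_type_spec("BLCA", n(300), driver_lambda = 13, passenger_mu = 45,
                     driver_gene_weights = zipf(c("TP53", "PIK3CA", "KMT2C", pool))),
    cancer_type_spec("PACA", n(400), driver_lambda = 4, passenger_mu = 30,
                     planted_gene_incidence = c(KRAS = 0.865, TP53 = 0.410),
                     driver_gene_weights = zipf(c("SMAD4", "TTN", pool))),
    cancer_type_spec("COCA", n(350), driver_lambda = 4, driver_lambda2 = 12,
                     mixture_weight = 0.45, passenger_mu = 40,
                     stage_multipliers = c(I = 1, II = 1.2, III = 1.5, IV = 1.9),
                     driver_gene_weights = zipf(c("APC", "KRAS", "TP53", pool))),
    cancer_type_spec("SKCM", n(300), driver_lambda = 8, passenger_mu = 120,
                     hypermutant_fraction = 0.01,
                     driver_gene_weights = zipf(c("BRAF", "NRAS", pool))),
    cancer_type_spec("PRAD", n(350), driver_lambda = 2, passenger_mu = 30,
                     stage_probs = c(I = 0.15, II = 0.5, III = 0.25, IV = 0.1),
                     stage_multipliers = c(I = 1, II = 1.5, III = 2, IV = 2.5),
                     driver_gene_weights = zipf(c("SPOP", "TP53", pool)))
  )
}

simulate_type <- function(spec, score_model, region) {
  n <- spec$n_samples
  sample_ids <- sprintf("%s_S%05d", spec$cancer_type, seq_len(n))
  stages <- names(spec$stage_probs)
  stage <- sample(stages, n, replace = TRUE, prob = spec$stage_probs)
  mult <- spec$stage_multipliers[stage]
  mult[is.na(mult)] <- 1  # unknown stage: no multiplier
  lambda <- rep(spec$driver_lambda, n)
  if (!is.null(spec$driver_lambda2)) {
    hi <- runif(n) < spec$mixture_weight
    lambda[hi] <- spec$driver_lambda2
  }
  lambda <- lambda * mult
  k_drivers <- rpois(n, lambda)
  hyper <- runif(n) < spec$hypermutant_fraction
  k_drivers[hyper] <- 501L + rpois(sum(hyper), spec$hypermutant_lambda)
  # planted genes: per sample, per gene, one extra driver with prob q
  planted <- spec$planted_gene_incidence
  planted_hits <- matrix(FALSE, n, length(planted))
  if (length(planted) > 0L) {
    for (j in seq_along(planted)) {
      planted_hits[, j] <- runif(n) < planted[j]
    }
  }
  k_planted <- if (length(planted)) rowSums(planted_hits) else rep(0L, n)
  m_passengers <- rpois(n, spec$passenger_mu)
  k_total <- k_drivers + k_planted
  n_var <- k_total + m_passengers

  total_drivers <- sum(k_total)
  total_pass <- sum(m_passengers)
  bg_genes <- if (sum(k_drivers) > 0L) {
    sample(names(spec$driver_gene_weights), sum(k_drivers),
           replace = TRUE, prob = spec$driver_gene_weights)
  } else character(0)
  pass_genes <- if (total_pass > 0L) {
    sample(spec$passenger_genes, total_pass, replace = TRUE)
  } else character(0)

  # assemble per-sample blocks: drivers (background then planted), passengers
  sample_rep <- rep.int(seq_len(n), n_var)
  is_driver <- unlist(lapply(seq_len(n), function(i) {
    rep(c(TRUE, FALSE), c(k_total[i], m_passengers[i]))
  }), use.names = FALSE)
  gene <- character(length(sample_rep))
  # fill genes: background drivers in draw order, planted genes explicit
  bg_i <- 0L
  pl <- if (length(planted)) names(planted) else character(0)
  gene_list <- vector("list", n)
  for (i in seq_len(n)) {
    g_bg <- if (k_drivers[i] > 0L) bg_genes[bg_i + seq_len(k_drivers[i])] else character(0)
    bg_i <- bg_i + k_drivers[i]
    g_pl <- if (length(planted)) pl[planted_hits[i, ]] else character(0)
    gene_list[[i]] <- c(g_bg, g_pl)
  }
  gene[is_driver] <- unlist(gene_list, use.names = FALSE)
  gene[!is_driver] <- pass_genes

  p_score <- numeric(length(sample_rep))
  p_score[is_driver] <- draw_scores(score_model, total_drivers, "driver")
  p_score[!is_driver] <- draw_scores(score_model, total_pass, "neutral")

  pos <- unlist(lapply(n_var, seq_len), use.names = FALSE)
  ref <- sample(NUCLEOTIDES, length(sample_rep), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(NUCLEOTIDES, r), 1L), character(1))

  records <- tibble::tibble(
    chrom = as.character(sample.int(22L, length(sample_rep), replace = TRUE)),
    pos = as.integer(pos),
    ref = ref, alt = alt,
    p_score = p_score,
    region = region,
    sample_id = sample_ids[sample_rep],
    cancer_type = spec$cancer_type,
    stage = ifelse(stage[sample_rep] == "unknown", NA_character_,
                   stage[sample_rep]),
    gene = gene
  )
  samples <- tibble::tibble(
    sample_id = sample_ids,
    cancer_type = spec$cancer_type,
    stage = ifelse(stage == "unknown", NA_character_, stage),
    true_driver_count = as.integer(k_total),
    n_passengers = as.integer(m_passengers),
    hypermutant = hyper
  )
  planted_truth <- if (length(planted)) {
    tibble::tibble(cancer_type = spec$cancer_type, gene = names(planted),
                   planted_incidence = as.numeric(planted),
                   realized_incidence = colMeans(planted_hits))
  } else NULL
  list(records = records, samples = samples, is_driver = is_driver,
       planted = planted_truth)
}

#' Simulate a multi-type tumour cohort with known ground truth
#'
#' For each sample of each cancer type, draws a true driver count `K` from
#' the configured Poisson (or mixture) model, a passenger count `M`, driver
#' p-scores from the driver score distribution, passenger p-scores from the
#' neutral distribution, and gene placements; hypermutant samples receive
#' driver counts above 500. Positions are synthesised as unique integers per
#' sample and play no computational role.
#'
#' @param model A [cohort_model()] (or single [cancer_type_spec()]).
#' @param score_model A [class_score_model()].
#' @param seed Integer seed; identical `(model, score_model, seed)` give
#'   identical output.
#' @param region Region tag for all records. Default `"coding"`.
#' @return A list with elements `records` (prediction-record tibble),
#'   `truth` (list: `samples` per-sample tibble with `true_driver_count` and
#'   `hypermutant`; `is_driver` logical vector aligned with `records` rows;
#'   `type_summary` per-type true mean/median driver count over
#'   non-hypermutant samples; `planted` planted-gene incidences).
#' @export
simulate_cohort <- function(model, score_model, seed = 1L,
                            region = "coding") {
  if (inherits(model, "cancer_type_spec")) model <- cohort_model(model)
  stopifnot(inherits(model, "cohort_model"),
            inherits(score_model, "class_score_model"))
  set.seed(seed)
  parts <- lapply(model, simulate_type, score_model = score_model,
                  region = region)
  records <- dplyr::bind_rows(lapply(parts, `[[`, "records"))
  samples <- dplyr::bind_rows(lapply(parts, `[[`, "samples"))
  is_driver <- unlist(lapply(parts, `[[`, "is_driver"), use.names = FALSE)
  planted <- dplyr::bind_rows(Filter(Negate(is.null),
                                     lapply(parts, `[[`, "planted")))
  type_summary <- samples |>
    dplyr::filter(!.data$hypermutant) |>
    dplyr::group_by(.data$cancer_type) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      true_mean = mean(.data$true_driver_count),
      true_median = median(.data$true_driver_count),
      .groups = "drop"
    )
  list(
    records = records,
    truth = list(samples = samples, is_driver = is_driver,
                 type_summary = type_summary, planted = planted)
  )
}

#' Analytic expectation of the weighted driver count per sample
#'
#' Independent oracle for the weighted counting rule: given the known class
#' score model and an estimated score histogram, computes the expected
#' per-sample weighted count by numerical integration over bins. A bin `b`
#' is eligible when its posterior exceeds 0.5; each eligible bin contributes
#' `(2*p_b - 1) * (mean_drivers * P_driver(b) + mean_passengers * P_neutral(b))`
#' where the class bin probabilities are integrated from the score model
#' (Beta tail differences, or indicators for point masses).
#'
#' @param score_model The [class_score_model()] the cohort scores are drawn
#'   from.
#' @param hist A `score_histogram` with posteriors estimated.
#' @param mean_drivers Expected true drivers per sample.
#' @param mean_passengers Expected passengers per sample.
#' @return The expected weighted count (deterministic).
#' @export
expected_weighted_count_oracle <- function(score_model, hist,
                                           mean_drivers, mean_passengers) {
  stopifnot(inherits(hist, "score_histogram"))
  if (is.null(hist$posterior)) {
    stop("histogram posteriors have not been estimated", call. = FALSE)
  }
  p_pos <- class_bin_probs(score_model, hist$bin_edges, "driver")
  p_neg <- class_bin_probs(score_model, hist$bin_edges, "neutral")
  post <- hist$posterior
  eligible <- !is.na(post) & post > 0.5
  sum((2 * post[eligible] - 1) *
        (mean_drivers * p_pos[eligible] + mean_passengers * p_neg[eligible]))
}
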