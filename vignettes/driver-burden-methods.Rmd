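---
title: "Estimating SNV driver burden: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating SNV driver burden: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driverburden)
```

## The estimation problem

A tumour genome carries many somatic single-nucleotide variants, of which
only a small subset are *drivers* — variants conferring selective growth
advantage. A binary classifier scores each observed variant with a
confidence `p` in [0, 1] (a *p-score*; 1 = maximal driver confidence,
0.5 the nominal decision boundary). Given per-variant p-scores for every
sample in a cohort, we want the per-sample count of SNV drivers — the
*tumour driver burden* (TDB) — and its distribution by cancer type, stage
and gene.

Two estimators are provided.

**Thresholded count.** Fix a cutoff `t` and count variants with
`p >= t`. The cutoff is chosen from a *balanced* labelled calibration set
(50:50 drivers and neutrals with known labels): for each candidate `t`,
the calibration tail counts `tp(t) = #{driver scores >= t}` and
`fp(t) = #{neutral scores >= t}` proxy true and false driver calls, and
`FDR(t) = fp / (tp + fp)`. We select the smallest grid threshold with
*sustained* control — `FDR(t') <= target` for every grid `t' >= t` at
which the FDR is defined — at a conservative target of 5%.

**Weighted (threshold-independent) count.** Bin the calibration scores
into bins of width 0.01. Within bin `b` the balanced class proportions
estimate the posterior `p_b = p(driver | called driver, score in b)`. A
cohort variant whose score lands in bin `b` is *eligible* when
`p_b > 0.5` (strict) and then contributes
`(+1) p_b + (-1)(1 - p_b) = 2 p_b - 1`; the weighted count is the sum of
contributions. This admits low-confidence calls, discounted by the
probability that they are false positives, and equals the expected number
of true-positive minus false-positive driver calls among eligible
variants — an identity the test suite asserts by recomputing both sides.

Both estimators assume the calibration set is class-balanced; that is why
`read_labeled_scores()` and `fdr_curve()` enforce a balance tolerance
(default 0.05) with an explicit override rather than silently accepting
imbalanced input, which would bias every posterior.

Samples with more than 500 drivers (strictly; a sample at exactly 500 is
retained) are flagged *hypermutant* and excluded before any cohort
statistic. The filter uses the thresholded count at the selected
threshold when one was applied — the filter precedes all reported
statistics in the pipeline order, and the thresholded count is the one
available at that point — otherwise the weighted count.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `target_fdr` | 0.05 | FDR target for threshold selection |
| `bin_width` | 0.01 | score histogram bin width (100 bins) |
| `hypermutation_max` | 500 drivers | strict exclusion cutoff |
| `threshold_grid` | 0, 0.01, …, 1 | candidate cutoffs (= bin edges) |
| `smoothing` | `add_one_isotonic` | posterior smoothing scheme |
| `mode_bin_width` | 1 count | bin width for the mode of weighted counts |

The threshold grid at 0.01 resolution matches the reporting resolution of
two-decimal thresholds; a finer grid would pretend to more calibration
resolution than 100-bin histograms provide.

## Posterior smoothing

Raw per-bin proportions at bin width 0.01 are noisy and undefined in
empty bins. Three schemes are offered:

* `none` — raw `pos / (pos + neg)`; empty bins are *undefined* and any
  cohort score landing in one raises an error naming the bin (silent
  fallbacks would hide calibration gaps);
* `add_one` — Laplace smoothing `(pos + 1)/(pos + neg + 2)`, shrinking
  empty bins to 1/2 (which makes them ineligible, a conservative default);
* `add_one_isotonic` (default) — add-one followed by a weighted
  pool-adjacent-violators pass, bins weighted by their smoothed totals
  `pos + neg + 2`. Platt-scaled classifier output should be monotone in
  the true posterior, so isotonisation is a shape constraint, not a
  modelling assumption. `stats::isoreg()` is unweighted, hence the small
  weighted PAVA implemented here; it agrees with `isoreg()` in the
  equal-weight case (tested).

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions
under which every estimator is validated, because the real prediction
databases and tumour cohorts behind the original analyses are external
resources, not desk-scale inputs.

* **Scores**: class-conditional Beta distributions — `Beta(8, 2)` for
  drivers, `Beta(2, 8)` for neutrals by default. Beta is supported on
  [0, 1] with flexible skew, a natural stand-in for empirical score
  histograms. These defaults describe a cleanly separable classifier
  (about 98% balanced accuracy at the 0.5 boundary) — deliberately
  stronger than realistic driver classifiers, whose coding accuracy is
  nearer 72% — so that a 5% FDR threshold exists comfortably inside the
  grid and posteriors span the full range; flatter shapes (e.g.
  `Beta(3, 2)` vs `Beta(2, 3)`) emulate weaker classifiers, and
  point-mass overrides pin each class to a single score for
  perfect-separation scenarios with exactly recoverable counts.
* **Counts**: per-sample true driver counts are Poisson(λ), or a
  two-component Poisson mixture for multi-modal ("neo-modal") cohorts;
  passengers are Poisson(μ). The generating literature offers no
  parametric form for these counts — Poisson is our modelling choice for
  "random in occurrence", not a claim inherited from data.
* **Stage**: assigned independently per sample from configured
  marginals; the driver rate is multiplied by a per-stage factor before
  sampling (all 1 = stage-constant). This is the simplest mechanism able
  to emulate both stage-constant types and monotone accumulation.
* **Hypermutants**: a configured fraction of samples receives
  `501 + Poisson(200)` drivers — always beyond the cutoff; only the
  cutoff, not the hypermutant count distribution, is defined by the
  analysis, so the excess distribution is arbitrary by design.
* **Genes**: each background driver is placed in a gene drawn by
  configurable selection weights (Zipf-like by default); passengers are
  uniform over a pool. *Planted* genes take a per-sample incidence
  `q` directly — with probability `q` the sample gains one extra driver
  in that gene — so a gene planted at 0.865 has exactly binomial
  incidence 0.865, which is what the gene-incidence recovery tests need.
* **Positions** are synthetic unique integers per sample; they play no
  computational role and carry no genomic realism.

What the generator does **not** emulate: mutational signatures,
trinucleotide context, chromosome placement, gene length (real
passenger hits concentrate in long genes such as TTN), intra-tumour
heterogeneity, and any dependence between a variant's score and its
sample context. Passing tests therefore show the *estimators* are
correct under the stated statistical structure; they do not show that
real cohorts satisfy that structure.

The default multi-type cohort (`default_cohort_model()`) spans the
qualitative range reported for common solid tumours: a 528-sample
thyroid-like type at λ = 0.8 with a dominant BRAF-like gene planted at
incidence 0.558, a breast-like type at λ = 6, a bladder-like type at
λ = 13 (the high end), a pancreatic-like type at λ = 4 with KRAS-like
(0.865) and TP53-like (0.410) planted genes, a colorectal-like bimodal
type (λ 4/12, stage-increasing), a melanoma-like type with heavy
passenger load and 1% hypermutants, and a prostate-like type with
monotone stage multipliers (1, 1.5, 2, 2.5).

## Numerical and procedural choices

* **Binning**: half-open bins `[kw, (k+1)w)` with the final bin closed at
  1. Bin lookup adds a 1e-9 relative tolerance before flooring so that a
  score lying on a bin edge (e.g. 0.91 at width 0.01, not exactly
  representable in floating point) lands in the bin it opens.
* **FDR from raw scores, not the histogram**: tail counts are computed
  from the labelled scores directly (exact), the histogram is used only
  for posteriors. Binned tails would quantise the curve for no benefit.
* **Sustained-control selection**: empirical FDR curves need not be
  monotone; requiring control at all larger grid thresholds (undefined
  bins skipped) is deterministic and conservative. If no threshold
  qualifies, selection returns `NA` with a warning rather than a guess.
* **Ties at the threshold**: `>= t` everywhere ("equal to or exceeding"),
  for counting, gene incidence and tail counts alike.
* **Quantiles**: the linear-interpolation rule (order statistic at
  `1 + (n - 1)p`; `quantile()` type 7). No quantile convention is
  canonical here; this is R's default and makes test fixtures exact.
* **Mode**: for integer counts, the most frequent value with ties to the
  smallest ("highest histogram peak" at bin width 1); for real-valued
  weighted counts, the midpoint of the fullest bin of configurable width
  (default 1) anchored at 0, ties leftmost. The binning behind reported
  modes of real-valued counts is genuinely underdetermined, so the width
  is exposed rather than hard-coded.
* **Mann-Whitney**: exact enumeration of all group assignments when
  `n_type + n_rest <= 12` (ties handled by midranks; identical multisets
  give p = 1), normal approximation with tie and continuity correction
  (`stats::wilcox.test`) above. Real cohorts are far beyond 12, so the
  approximation is the operational path; the exact path exists for
  testability and is cross-checked against `wilcox.test(exact = TRUE)`
  and a brute-force permutation oracle on tie-free cases. The default
  input is the thresholded count at the FDR-selected threshold — which
  count the comparison "should" use is underdetermined, and the
  thresholded one is the pipeline's primary statistic.
* **Threshold sweeps** re-apply the hypermutation filter at every grid
  point, since hypermutant status depends on the threshold. A
  consequence worth knowing: at high thresholds a formerly hypermutant
  sample can re-enter the retained set with a large count, so per-type
  mean curves are guaranteed non-increasing only over a fixed sample set
  (the monotonicity tests use hypermutant-free cohorts for this reason).
* **Gene incidence denominators** include every sample of the type
  present in the cohort, including samples with no qualifying variant
  anywhere (incidence "of samples", not "of mutated samples"). Gene
  symbols are matched as exact strings. Samples with zero variants can
  be carried explicitly via the `samples` argument of `driver_counts()`.
* **Stage tables** omit empty stages rather than zero-filling, and
  exclude unknown-stage samples with a reported tally.
  `monotone_medians` treats ties as non-decreasing, so stage-constant
  types frequently satisfy it; the analysis scripts therefore look at
  the spread of stage medians, not the flag alone.

## Validation problem sizes

The test suite validates each estimator at sizes chosen to make the
statistical tolerances sharp while keeping the full run in the minutes
range: calibration recovery at 50,000 scores per class; posterior
recovery against the analytic Beta posterior at 10^6 draws per class
(within 0.05 on every bin with analytic mass >= 10^-3); exact-recovery
cohorts of 5,000 samples under point-mass scores; weighted-estimator
versus analytic-oracle agreement over 10,000 simulated samples at three
driver rates (λ = 1, 4, 12; μ = 20) within 3 Monte-Carlo standard
errors; differentiation power at 500 samples per type (λ = 1 vs 8,
p < 10^-10); gene-incidence recovery at 4,000 samples within 3 binomial
standard errors; and stage-trend recovery at 8,000 samples across 10
seeds.

## Known limitations

* The estimators inherit the classifier's calibration: posteriors and
  FDR are only as good as the balance and representativeness of the
  labelled score set. With a heavily imbalanced *population* (drivers
  are rare among all observed variants), a balanced-trained classifier
  over-calls the positive class, so thresholded counts at permissive
  cutoffs are upward-biased — visible here as type means sitting above
  the generating λ at the 5% FDR threshold, while the weighted estimator
  (which subtracts expected false positives) lands closer.
* The weighted count uses the same 0.01 binning as calibration rather
  than per-record kernel estimates; this matches the calibration
  resolution and keeps the analytic oracle tractable, at the cost of
  step-function granularity.
* No multi-modality deconvolution is attempted: bimodal types are
  summarised by primary mode/median/mean only.
* No trend test across stages is performed; stage tables are
  descriptive.
* Coordinates are carried (1-based, point positions) but never used in
  arithmetic; there is no liftover, reference validation or annotation.
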