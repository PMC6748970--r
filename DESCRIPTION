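Package: driverburden
Title: Estimating Somatic SNV Driver Burden in Tumour Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-sample counts of single-nucleotide-variant (SNV)
    drivers in tumour cohorts from classifier confidence scores (p-scores).
    Calibrates a p-score threshold at a target false discovery rate from a
    balanced labelled score set, counts drivers per sample both by
    thresholding and by a threshold-independent posterior-weighted scheme,
    filters hypermutant samples, summarises driver burden by cancer type and
    clinical stage (mode, median, mean, quartiles, Mann-Whitney
    differentiation), and ranks driver genes by the fraction of samples
    carrying at least one high-confidence driver. Includes a synthetic
    cohort generator with known ground truth for validating the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
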