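# Tabular I/O for cohort prediction tables, calibration score sets and
# summary tables. All tables are plain TSV (tab-separated, UTF-8, '#' comment
# lines skipped, mandatory header); missing stage/gene are encoded ".".

PREDICTION_COLUMNS <- c("chrom", "pos", "ref", "alt", "p_score", "region",
                        "sample_id", "cancer_type", "stage", "gene")
VALID_REGIONS <- c("coding", "noncoding")
VALID_STAGES <- c("I", "II", "III", "IV")
NUCLEOTIDES <- c("A", "C", "G", "T")

# INFO keys of the single-sample-per-record VCF dialect
VCF_INFO_KEYS <- c(p_score = "PSCORE", region = "RGN", sample_id = "SMP",
                   cancer_type = "CTYPE", stage = "STG", gene = "GENE")

#' Read a cohort prediction table
#'
#' Reads per-variant driver predictions for a tumour cohort: one row per
#' (sample, variant) pair carrying the classifier p-score plus sample
#' annotations. Two renderings are supported: a TSV with columns
#' `chrom, pos, ref, alt, p_score, region, sample_id, cancer_type, stage,
#' gene` (missing stage/gene as `"."`), and a VCF dialect with one
#' variant-sample pair per record and INFO keys `PSCORE`, `RGN`, `SMP`,
#' `CTYPE`, `STG`, `GENE`.
#'
#' Validation errors name the offending field and the 1-based data row
#' (header and `#` comment lines excluded from the row count).
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @return A tibble of validated prediction records; `stage` and `gene` are
#'   `NA` where missing. Row order of the file is preserved.
#' @export
read_predictions <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- switch(format,
    tsv = read_predictions_tsv(path),
    vcf = read_predictions_vcf(path)
  )
  validate_predictions(df)
}

read_predictions_tsv <- function(path) {
  df <- readr::read_tsv(
    path,
    comment = "#",
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_double(),
      ref = readr::col_character(),
      alt = readr::col_character(),
      p_score = readr::col_double(),
      region = readr::col_character(),
      sample_id = readr::col_character(),
      cancer_type = readr::col_character(),
      stage = readr::col_character(),
      gene = readr::col_character()
    ),
    na = character(),
    progress = FALSE
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    stop(sprintf("malformed row %d: %s (got '%s')",
                 probs$row[1], probs$expected[1], probs$actual[1]),
         call. = FALSE)
  }
  missing_cols <- setdiff(PREDICTION_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("prediction table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[PREDICTION_COLUMNS]
  if (nrow(df) == 0L) {
    warning("prediction table ", path, " contains a header but no records",
            call. = FALSE)
  }
  df$stage[df$stage == "." | df$stage == "unknown"] <- NA_character_
  df$gene[df$gene == "."] <- NA_character_
  tibble::as_tibble(df)
}

read_predictions_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  info_of <- function(key) {
    vals <- vcfR::extract.info(vcf, element = key)
    if (is.null(vals)) rep(NA_character_, nrow(fix)) else as.character(vals)
  }
  df <- tibble::tibble(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.numeric(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    p_score = suppressWarnings(as.numeric(info_of("PSCORE"))),
    region = info_of("RGN"),
    sample_id = info_of("SMP"),
    cancer_type = info_of("CTYPE"),
    stage = info_of("STG"),
    gene = info_of("GENE")
  )
  df$stage[!is.na(df$stage) & (df$stage == "." | df$stage == "unknown")] <- NA_character_
  df$gene[!is.na(df$gene) & df$gene == "."] <- NA_character_
  df
}

#' Validate a tibble of prediction records
#'
#' Checks field domains (p-score in \[0, 1\], single-nucleotide ref/alt with
#' ref != alt, known region token, pos >= 1) and the uniqueness of
#' (sample_id, chrom, pos, ref, alt) within the table. Errors name the field
#' and the first offending data row.
#'
#' @param df A tibble with the prediction-table columns.
#' @return The validated tibble, invisibly coerced column types.
#' @export
validate_predictions <- function(df) {
  fail <- function(field, rows, msg) {
    stop(sprintf("invalid %s at row %d: %s", field, rows[1], msg),
         call. = FALSE)
  }
  bad <- which(is.na(df$p_score))
  if (length(bad)) fail("p_score", bad, "not numeric")
  bad <- which(df$p_score < 0 | df$p_score > 1)
  if (length(bad)) {
    fail("p_score", bad,
         sprintf("value %g outside [0, 1]", df$p_score[bad[1]]))
  }
  bad <- which(!df$region %in% VALID_REGIONS)
  if (length(bad)) {
    fail("region", bad, sprintf("unknown token '%s'", df$region[bad[1]]))
  }
  bad <- which(is.na(df$pos) | df$pos < 1 | df$pos != floor(df$pos))
  if (length(bad)) fail("pos", bad, "must be a positive integer")
  bad <- which(!df$ref %in% NUCLEOTIDES)
  if (length(bad)) fail("ref", bad, sprintf("'%s' is not a single nucleotide", df$ref[bad[1]]))
  bad <- which(!df$alt %in% NUCLEOTIDES)
  if (length(bad)) fail("alt", bad, sprintf("'%s' is not a single nucleotide", df$alt[bad[1]]))
  bad <- which(df$ref == df$alt)
  if (length(bad)) fail("alt", bad, "alt must differ from ref")
  bad <- which(!is.na(df$stage) & !df$stage %in% VALID_STAGES)
  if (length(bad)) fail("stage", bad, sprintf("unknown token '%s'", df$stage[bad[1]]))
  key <- paste(df$sample_id, df$chrom, df$pos, df$ref, df$alt, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    fail("record", dup, "(sample_id, chrom, pos, ref, alt) duplicated")
  }
  df$pos <- as.integer(df$pos)
  tibble::as_tibble(df)
}

#' Write a cohort prediction table
#'
#' Renders prediction records as the TSV or VCF dialect that
#' [read_predictions()] reads back. Missing stage/gene are written `"."` in
#' TSV and omitted from INFO in VCF.
#'
#' @param records Tibble of prediction records.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @param comments Optional character vector written as leading `#` comment
#'   lines (TSV) or `##` meta lines (VCF).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(records, path, format = c("tsv", "vcf"),
                              comments = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- records[PREDICTION_COLUMNS]
    out$stage[is.na(out$stage)] <- "."
    out$gene[is.na(out$gene)] <- "."
    con <- file(path, "w")
    on.exit(close(con))
    for (cm in comments) writeLines(paste0("# ", cm), con)
    writeLines(paste(PREDICTION_COLUMNS, collapse = "\t"), con)
    body <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
    if (length(body)) writeLines(body, con)
  } else {
    info <- sprintf("PSCORE=%s;RGN=%s;SMP=%s;CTYPE=%s",
                    format(records$p_score, trim = TRUE, digits = 10),
                    records$region, records$sample_id, records$cancer_type)
    info <- ifelse(is.na(records$stage), info,
                   paste0(info, ";STG=", records$stage))
    info <- ifelse(is.na(records$gene), info,
                   paste0(info, ";GENE=", records$gene))
    hdr <- c(
      "##fileformat=VCFv4.2",
      paste0("##", comments),
      '##INFO=<ID=PSCORE,Number=1,Type=Float,Description="Driver p-score">',
      '##INFO=<ID=RGN,Number=1,Type=String,Description="coding or noncoding">',
      '##INFO=<ID=SMP,Number=1,Type=String,Description="Sample id">',
      '##INFO=<ID=CTYPE,Number=1,Type=String,Description="Cancer type code">',
      '##INFO=<ID=STG,Number=1,Type=String,Description="Stage I-IV">',
      '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
    )
    if (is.null(comments)) hdr <- hdr[hdr != "##"]
    body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                  ".", ".", info, sep = "\t")
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Read a labelled calibration score set
#'
#' Reads the balanced labelled score set used to calibrate posteriors and the
#' FDR curve: a TSV with columns `p_score`, `label`, `region`. Labels may be
#' `driver`/`neutral` or the aliases `+1`/`-1`. The set must be approximately
#' class-balanced (the posterior and FDR estimators assume 50:50 calibration
#' data): the read fails if `|#driver - #neutral| / n` exceeds
#' `balance_tolerance`, unless `enforce_balance = FALSE`.
#'
#' @param path Path to the TSV.
#' @param balance_tolerance Maximal allowed class imbalance. Default 0.05.
#' @param enforce_balance If `FALSE`, imbalance only warns.
#' @return A tibble with columns `p_score` (numeric), `label`
#'   (`"driver"`/`"neutral"`) and `region`.
#' @export
read_labeled_scores <- function(path, balance_tolerance = 0.05,
                                enforce_balance = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(
    path, comment = "#",
    col_types = readr::cols(
      p_score = readr::col_double(),
      label = readr::col_character(),
      region = readr::col_character()
    ),
    progress = FALSE
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    stop(sprintf("malformed row %d: %s (got '%s')",
                 probs$row[1], probs$expected[1], probs$actual[1]),
         call. = FALSE)
  }
  validate_labeled_scores(df, balance_tolerance = balance_tolerance,
                          enforce_balance = enforce_balance)
}

#' Validate a labelled calibration score set
#'
#' @param df Tibble with columns `p_score`, `label`, `region`.
#' @inheritParams read_labeled_scores
#' @return Validated tibble with labels normalised to `driver`/`neutral`.
#' @export
validate_labeled_scores <- function(df, balance_tolerance = 0.05,
                                    enforce_balance = TRUE) {
  df$label[df$label == "+1"] <- "driver"
  df$label[df$label == "-1"] <- "neutral"
  bad <- which(!df$label %in% c("driver", "neutral"))
  if (length(bad)) {
    stop(sprintf("invalid label at row %d: unknown token '%s'",
                 bad[1], df$label[bad[1]]), call. = FALSE)
  }
  bad <- which(is.na(df$p_score) | df$p_score < 0 | df$p_score > 1)
  if (length(bad)) {
    stop(sprintf("invalid p_score at row %d: outside [0, 1]", bad[1]),
         call. = FALSE)
  }
  bad <- which(!df$region %in% VALID_REGIONS)
  if (length(bad)) {
    stop(sprintf("invalid region at row %d: unknown token '%s'",
                 bad[1], df$region[bad[1]]), call. = FALSE)
  }
  n_pos <- sum(df$label == "driver")
  n_neg <- sum(df$label == "neutral")
  imbalance <- abs(n_pos - n_neg) / max(1L, nrow(df))
  if (imbalance > balance_tolerance) {
    msg <- sprintf(
      "calibration set is imbalanced: %d driver vs %d neutral (imbalance %.3f > tolerance %.3f)",
      n_pos, n_neg, imbalance, balance_tolerance)
    if (enforce_balance) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write a summary table as TSV
#'
#' Writes any pipeline summary table with a deterministic column order
#' (as given), a mandatory header, optional leading `#` comment lines
#' recording the configuration used, and numeric columns rendered at 6
#' significant digits so that a read-back reproduces the values to that
#' precision. Writing an empty table is an error, not an empty file.
#'
#' @param table A non-empty data frame.
#' @param path Output path.
#' @param comments Optional character vector of comment lines.
#' @return `path`, invisibly.
#' @export
write_summary <- function(table, path, comments = NULL) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("refusing to write an empty summary table", call. = FALSE)
  }
  out <- as.data.frame(table)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(signif(out[[j]], 6), format = "g", digits = 6)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  writeLines(paste(names(out), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(out, as.character), sep = "\t")), con)
  invisible(path)
}

#' Read back a summary table written by [write_summary()]
#'
#' @param path Path to the TSV.
#' @return A tibble; columns are type-guessed.
#' @export
read_summary <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
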