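# Reading, validation and writing of GWAS summary statistics and MR result
# tables. One row of summary statistics describes one SNP-trait association:
# identifier, location, allele pair, effect-allele frequency, effect size
# (log-odds for binary traits, standardized units for continuous ones),
# standard error, p-value and sample size.

REQUIRED_FIELDS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                     "beta", "se", "pval")
ALL_FIELDS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")

#' Default summary-statistics column mapping
#'
#' Maps internal field names to the column names most GWAS distribution files
#' use (SNP, CHR, BP, A1, A2, EAF, BETA, SE, P, N). Pass a modified copy to
#' [read_sumstats()] for files with other headers.
#'
#' @return Named character vector; names are internal fields, values are file
#'   column names.
#' @export
default_column_map <- function() {
  c(snp_id = "SNP", chrom = "CHR", pos = "BP",
    effect_allele = "A1", other_allele = "A2",
    eaf = "EAF", beta = "BETA", se = "SE", pval = "P", n = "N")
}

#' Construct a validated summary-statistics object
#'
#' Validates per-row invariants (distinct A/C/G/T alleles, positive SE,
#' p-value in (0, 1], frequency strictly inside (0, 1) when present, unique
#' SNP identifiers), uppercases alleles, and keeps an audit of rejected rows
#' with one reason each.
#'
#' @param records Data frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval` and optionally
#'   `eaf` and `n`.
#' @param trait_name Trait label, e.g. `"E2"` or `"CD"`.
#' @param trait_type `"continuous"` or `"binary"`. Binary-trait effects are
#'   interpreted on the log-odds scale.
#' @param stratum `"all"`, `"male"` or `"female"`.
#' @return An object of class `summary_stats`: a list with `trait_name`,
#'   `trait_type`, `stratum`, `records` (validated rows, input order
#'   preserved) and `rejected` (rows dropped, with a `reason` column).
#' @export
summary_stats <- function(records, trait_name,
                          trait_type = c("continuous", "binary"),
                          stratum = c("all", "male", "female")) {
  trait_type <- match.arg(trait_type)
  stratum <- match.arg(stratum)
  stopifnot(is.data.frame(records))

  missing_cols <- setdiff(REQUIRED_FIELDS, names(records))
  if (length(missing_cols) > 0) {
    mr_abort("mr_config_error",
             sprintf("summary statistics for '%s' lack mandatory column(s): %s",
                     trait_name, paste(missing_cols, collapse = ", ")))
  }
  if (!"eaf" %in% names(records)) records$eaf <- NA_real_
  if (!"n" %in% names(records)) records$n <- NA_real_
  records <- records[, ALL_FIELDS]

  records$snp_id <- as.character(records$snp_id)
  records$chrom <- as.character(records$chrom)
  records$pos <- as.numeric(records$pos)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
  }

  reason <- rep(NA_character_, nrow(records))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    ifelse(is.na(reason) & bad, why, reason)
  }
  bases <- c("A", "C", "G", "T")
  reason <- flag(is.na(records$snp_id) | records$snp_id == "", "missing snp_id")
  reason <- flag(!(records$effect_allele %in% bases) |
                   !(records$other_allele %in% bases), "invalid allele")
  reason <- flag(records$effect_allele == records$other_allele,
                 "identical alleles")
  reason <- flag(!is.finite(records$beta), "missing beta")
  reason <- flag(!is.finite(records$se) | records$se <= 0, "nonpositive se")
  reason <- flag(!is.finite(records$pval) | records$pval <= 0 |
                   records$pval > 1, "pval out of range")
  eaf_bad <- !is.na(records$eaf) & (records$eaf <= 0 | records$eaf >= 1)
  reason <- ifelse(is.na(reason) & eaf_bad, "eaf out of range", reason)
  n_bad <- !is.na(records$n) & records$n <= 0
  reason <- ifelse(is.na(reason) & n_bad, "nonpositive n", reason)
  dup <- duplicated(records$snp_id)
  reason <- ifelse(is.na(reason) & dup, "duplicate snp_id", reason)

  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  kept <- records[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  rownames(rejected) <- NULL

  structure(
    list(trait_name = trait_name, trait_type = trait_type, stratum = stratum,
         records = kept, rejected = rejected),
    class = "summary_stats"
  )
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> %s (%s, %s): %d SNPs (%d rejected)\n",
              x$trait_name, x$trait_type, x$stratum,
              nrow(x$records), nrow(x$rejected)))
  invisible(x)
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or comma-delimited table (delimiter auto-detected from the
#' header line), renames columns through `column_map`, and validates rows via
#' [summary_stats()]. Rows violating any field invariant are dropped and
#' logged in the returned object's `rejected` slot with a per-row reason;
#' alleles are uppercased.
#'
#' @inheritParams summary_stats
#' @param path Path to the file.
#' @param column_map Named character vector mapping internal field names to
#'   file column names; see [default_column_map()]. `eaf` and `n` entries may
#'   be absent from the file.
#' @return A `summary_stats` object.
#' @export
read_sumstats <- function(path, trait_name,
                          trait_type = c("continuous", "binary"),
                          stratum = c("all", "male", "female"),
                          column_map = default_column_map()) {
  if (!file.exists(path)) {
    mr_abort("mr_io_error", sprintf("file not found: %s", path))
  }
  raw <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  mandatory <- setdiff(REQUIRED_FIELDS, c("eaf", "n"))
  miss <- setdiff(unname(column_map[mandatory]), names(raw))
  if (length(miss) > 0) {
    mr_abort("mr_config_error",
             sprintf("'%s' lacks mandatory column(s): %s", path,
                     paste(miss, collapse = ", ")))
  }
  present <- column_map[column_map %in% names(raw)]
  records <- raw[, unname(present), drop = FALSE]
  names(records) <- names(present)

  out <- summary_stats(records, trait_name = trait_name,
                       trait_type = trait_type, stratum = stratum)
  if (nrow(out$records) == 0) {
    mr_abort("mr_empty_input",
             sprintf("no valid rows in '%s' for trait '%s'", path, trait_name))
  }
  out
}

#' Write summary statistics back to a delimited file
#'
#' Inverse of [read_sumstats()] for the validated record set; reading the
#' written file recovers the records field-for-field.
#'
#' @param stats A `summary_stats` object.
#' @param path Output path; extension `.csv` selects comma delimiting,
#'   anything else tab.
#' @param column_map Field-to-column mapping used for the header.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path, column_map = default_column_map()) {
  stopifnot(inherits(stats, "summary_stats"))
  out <- stats$records
  keep <- names(column_map)[names(column_map) %in% names(out)]
  out <- out[, keep]
  names(out) <- unname(column_map[keep])
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

RESULT_COLUMNS <- c("exposure", "outcome", "stratum", "direction", "method",
                    "n_snp", "beta", "se", "or_", "ci_low", "ci_high", "pval",
                    "robust_flag", "display")

METHOD_ORDER <- c("ivw_re", "egger", "weighted_median", "wald_ratio")
METHOD_LABELS <- c(ivw_re = "IVW", egger = "MR-Egger",
                   weighted_median = "Weighted median",
                   wald_ratio = "Wald ratio")

#' Write an MR results table
#'
#' One row per (exposure, outcome, stratum, direction, method). Rows are
#' ordered by analysis unit and, within a unit, by method (IVW, MR-Egger,
#' weighted median, then Wald ratio). Numeric columns are written at full
#' double precision; a human-readable 3-decimal `display` column is appended.
#' For binary outcomes `ci_low`/`ci_high` are the 95% bounds of the odds
#' ratio; for continuous outcomes they are the bounds of `beta` and `or_` is
#' empty.
#'
#' @param results Data frame with columns `exposure`, `outcome`, `stratum`,
#'   `direction`, `method`, `n_snp`, `beta`, `se`, `or_`, `ci_low`,
#'   `ci_high`, `pval`, `robust_flag` (see [results_table()]).
#' @param path Output path (`.csv` for comma-delimited, else tab).
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  need <- setdiff(RESULT_COLUMNS, c("display"))
  miss <- setdiff(need, names(results))
  if (length(miss) > 0) {
    mr_abort("mr_config_error",
             sprintf("results table lacks column(s): %s",
                     paste(miss, collapse = ", ")))
  }
  ord <- order(results$exposure, results$outcome, results$stratum,
               results$direction,
               match(results$method, METHOD_ORDER))
  results <- results[ord, , drop = FALSE]
  results$display <- ifelse(
    is.na(results$beta), "not estimable",
    ifelse(!is.na(results$or_),
           sprintf("OR=%.3f (%.3f, %.3f), P=%.3f",
                   results$or_, results$ci_low, results$ci_high, results$pval),
           sprintf("beta=%.3f (%.3f, %.3f), P=%.3f",
                   results$beta, results$ci_low, results$ci_high, results$pval)))
  out <- results[, RESULT_COLUMNS]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), NA, sprintf("%.17g", x))
  })
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  ok <- try(utils::write.table(out, path, sep = sep, quote = FALSE,
                               row.names = FALSE, na = ""), silent = TRUE)
  if (inherits(ok, "try-error")) {
    mr_abort("mr_io_error", sprintf("cannot write results to '%s'", path))
  }
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path Path to the file.
#' @return Data frame with numeric columns restored.
#' @export
read_results_table <- function(path) {
  res <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", na.strings = "")
  for (col in c("n_snp", "beta", "se", "or_", "ci_low", "ci_high", "pval")) {
    res[[col]] <- as.numeric(res[[col]])
  }
  res$robust_flag <- as.logical(res$robust_flag)
  res
}
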