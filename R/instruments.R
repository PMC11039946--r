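# Instrumental-variable selection: genome-wide significance threshold with a
# relaxed fallback when fewer than two SNPs survive clumping, greedy LD
# clumping (r^2 < 0.001 within a 10,000 kb window), and an instrument-strength
# filter F = beta^2 / se^2 > 10.

#' Per-SNP instrument-strength F statistic
#'
#' F = beta^2 / se^2, the square of the exposure-association z score; values
#' strictly above 10 are conventionally taken to rule out weak-instrument
#' bias.
#'
#' @param beta,se Exposure effect estimates and their standard errors
#'   (vectorized).
#' @return Numeric vector of F values.
#' @examples
#' f_statistic(0.1, 0.01)  # 100
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se) | se <= 0)) {
    mr_abort("mr_domain_error", "f_statistic requires se > 0")
  }
  (beta / se)^2
}

validate_ld <- function(ld) {
  if (is.null(ld)) return(invisible(NULL))
  if (!is.matrix(ld) || nrow(ld) != ncol(ld) ||
      is.null(rownames(ld)) || !identical(rownames(ld), colnames(ld))) {
    mr_abort("mr_config_error",
             "LD matrix must be square with identical SNP row/column names")
  }
  if (!isTRUE(all.equal(ld, t(ld), tolerance = 1e-8))) {
    mr_abort("mr_config_error", "LD matrix must be symmetric")
  }
  if (any(abs(diag(ld) - 1) > 1e-8)) {
    mr_abort("mr_config_error", "LD matrix diagonal must be 1")
  }
  if (any(abs(ld) > 1 + 1e-8)) {
    mr_abort("mr_config_error", "LD correlations must lie in [-1, 1]")
  }
  invisible(NULL)
}

#' Greedy LD clumping of summary-statistics records
#'
#' Repeatedly keeps the unprocessed SNP with the smallest p-value (ties
#' broken by genomic coordinate, then lexicographic identifier) and removes
#' every unprocessed SNP on the same chromosome within `window_kb` whose
#' squared correlation with it is at least `r2_max`. The result is therefore
#' independent of input row order, and clumping an already-clumped set is a
#' no-op.
#'
#' @param records Data frame with columns `snp_id`, `chrom`, `pos`, `pval`.
#' @param ld Symmetric correlation matrix with SNP dimnames, or `NULL` for
#'   no LD information. SNPs absent from `ld` are treated as unlinked (a
#'   note is emitted when `ld` is non-`NULL`).
#' @param r2_max Squared-correlation threshold (pairs at or above it are
#'   clumped together).
#' @param window_kb Window in kilobases; SNPs at most this far apart are in
#'   the same clumping window.
#' @return The surviving records, sorted by chromosome then position.
#' @export
clump <- function(records, ld = NULL, r2_max = 0.001, window_kb = 10000) {
  validate_ld(ld)
  if (nrow(records) == 0) return(records)
  if (!is.null(ld)) {
    absent <- setdiff(records$snp_id, rownames(ld))
    if (length(absent) > 0) {
      message(sprintf("clump: %d SNP(s) absent from LD matrix, treated as unlinked",
                      length(absent)))
    }
  }
  chrom_num <- suppressWarnings(as.numeric(records$chrom))
  chrom_key <- ifelse(is.na(chrom_num), 1e6 + match(records$chrom,
                                                    sort(unique(records$chrom))),
                      chrom_num)
  ord <- order(records$pval, chrom_key, records$pos, records$snp_id)
  alive <- rep(TRUE, nrow(records))
  keep <- logical(nrow(records))
  window_bp <- window_kb * 1000
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    near <- which(alive & records$chrom == records$chrom[i] &
                    abs(records$pos - records$pos[i]) <= window_bp)
    if (length(near) == 0 || is.null(ld)) next
    if (!(records$snp_id[i] %in% rownames(ld))) next
    in_ld <- near[records$snp_id[near] %in% rownames(ld)]
    if (length(in_ld) == 0) next
    r2 <- ld[records$snp_id[i], records$snp_id[in_ld]]^2
    alive[in_ld[r2 >= r2_max]] <- FALSE
  }
  out <- records[keep, , drop = FALSE]
  out <- out[order(chrom_key[keep], out$pos, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Significance filtering with clumping and fallback threshold
#'
#' Applies the primary genome-wide threshold, clumps, and — if fewer than
#' `post_clump_min` SNPs survive — restarts from the full table at the
#' relaxed fallback threshold. The threshold actually used is recorded.
#'
#' @param stats A [summary_stats()] object for the exposure.
#' @param ld,r2_max,window_kb Passed to [clump()].
#' @param p_primary,p_fallback Primary and fallback p-value thresholds
#'   (strict `<` comparisons).
#' @param post_clump_min Minimum clumped set size before falling back.
#' @return List with `records` (filtered, clumped), `threshold_used`, and
#'   `pre_clump` (records passing the used threshold before clumping).
#' @export
filter_by_pvalue <- function(stats, ld = NULL, p_primary = 5e-8,
                             p_fallback = 5e-6, post_clump_min = 2,
                             r2_max = 0.001, window_kb = 10000) {
  stopifnot(inherits(stats, "summary_stats"))
  records <- stats$records
  if (nrow(records) == 0) {
    mr_abort("mr_no_instruments",
             sprintf("no SNPs available for exposure '%s'", stats$trait_name))
  }
  s1 <- records[records$pval < p_primary, , drop = FALSE]
  c1 <- clump(s1, ld = ld, r2_max = r2_max, window_kb = window_kb)
  if (nrow(c1) >= post_clump_min) {
    return(list(records = c1, threshold_used = p_primary, pre_clump = s1))
  }
  s2 <- records[records$pval < p_fallback, , drop = FALSE]
  c2 <- clump(s2, ld = ld, r2_max = r2_max, window_kb = window_kb)
  if (nrow(c2) == 0) {
    mr_abort("mr_no_instruments",
             sprintf("no instruments for exposure '%s' even at p < %g",
                     stats$trait_name, p_fallback))
  }
  list(records = c2, threshold_used = p_fallback, pre_clump = s2)
}

#' Select instrumental variables for an exposure
#'
#' Full selection chain: significance threshold (with fallback), greedy LD
#' clumping, then the strict F > `f_min` strength filter. Every input SNP's
#' disposition is recorded in an audit table (`kept`, `dropped_pval`,
#' `dropped_ld`, `dropped_weak`), evaluated against the threshold actually
#' used.
#'
#' @inheritParams filter_by_pvalue
#' @param f_min Minimum F statistic; kept SNPs have F strictly greater.
#' @return Object of class `instrument_set`: `exposure_name`, `records`
#'   (kept SNPs with an `f_stat` column, sorted by chromosome and position),
#'   `f_stats`, `threshold_used`, `audit`.
#' @export
select_instruments <- function(stats, ld = NULL, p_primary = 5e-8,
                               p_fallback = 5e-6, post_clump_min = 2,
                               r2_max = 0.001, window_kb = 10000,
                               f_min = 10) {
  fp <- filter_by_pvalue(stats, ld = ld, p_primary = p_primary,
                         p_fallback = p_fallback,
                         post_clump_min = post_clump_min,
                         r2_max = r2_max, window_kb = window_kb)
  kept <- fp$records
  kept$f_stat <- f_statistic(kept$beta, kept$se)
  strong <- kept[kept$f_stat > f_min, , drop = FALSE]
  if (nrow(strong) == 0) {
    mr_abort("mr_no_instruments",
             sprintf("all instruments for exposure '%s' are weak (F <= %g)",
                     stats$trait_name, f_min))
  }
  all_ids <- stats$records$snp_id
  disposition <- rep("dropped_pval", length(all_ids))
  disposition[all_ids %in% fp$pre_clump$snp_id] <- "dropped_ld"
  disposition[all_ids %in% kept$snp_id] <- "dropped_weak"
  disposition[all_ids %in% strong$snp_id] <- "kept"
  audit <- data.frame(snp_id = all_ids, disposition = disposition,
                      stringsAsFactors = FALSE)
  rownames(strong) <- NULL
  structure(
    list(exposure_name = stats$trait_name, exposure_type = stats$trait_type,
         stratum = stats$stratum, records = strong,
         f_stats = stats::setNames(strong$f_stat, strong$snp_id),
         threshold_used = fp$threshold_used, audit = audit,
         filter_order = c("pvalue", "clump", "f_statistic")),
    class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s: %d instruments (p < %g, min F = %.1f)\n",
              x$exposure_name, nrow(x$records), x$threshold_used,
              min(x$records$f_stat)))
  invisible(x)
}
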