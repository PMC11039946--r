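# Harmonization: align outcome records to the exposure effect allele and
# exclude palindromic variants. Palindromic SNPs (A/T, C/G) are dropped
# unconditionally — no frequency-based strand inference — and SNPs absent
# from the outcome are dropped without proxy lookup.

HARMONIZE_ACTIONS <- c("kept_same", "kept_flipped", "dropped_palindromic",
                       "dropped_missing", "dropped_mismatch")

#' Harmonize an instrument set against an outcome GWAS
#'
#' Per instrument SNP, in order: (a) absent from the outcome table ->
#' `dropped_missing`; (b) palindromic allele pair on either side ->
#' `dropped_palindromic`; (c) outcome alleles identical to the exposure's ->
#' `kept_same`; (d) outcome alleles swapped -> `kept_flipped`, with the
#' outcome beta negated and its frequency complemented; (e) anything else ->
#' `dropped_mismatch`.
#'
#' @param instruments An [select_instruments()] result.
#' @param outcome A [summary_stats()] object for the outcome.
#' @param direction `"forward"` or `"reverse"`, carried through to reporting.
#' @return Object of class `harmonized_data`: `exposure_name`,
#'   `outcome_name`, `stratum`, `direction`, `outcome_type`, `records` (kept
#'   SNPs: `snp_id`, `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf_out`,
#'   `action`) and `audit` (every instrument SNP with its action).
#' @export
harmonize_pair <- function(instruments, outcome,
                           direction = c("forward", "reverse")) {
  stopifnot(inherits(instruments, "instrument_set"),
            inherits(outcome, "summary_stats"))
  direction <- match.arg(direction)
  ins <- instruments$records
  if (nrow(ins) == 0) {
    mr_abort("mr_no_instruments", "instrument set is empty")
  }
  out <- outcome$records
  idx <- match(ins$snp_id, out$snp_id)

  action <- rep(NA_character_, nrow(ins))
  beta_out <- se_out <- eaf_out <- rep(NA_real_, nrow(ins))

  missing <- is.na(idx)
  action[missing] <- "dropped_missing"

  has <- which(!missing)
  o <- out[idx[has], , drop = FALSE]
  pal <- is_palindromic(ins$effect_allele[has], ins$other_allele[has]) |
    is_palindromic(o$effect_allele, o$other_allele)
  same <- o$effect_allele == ins$effect_allele[has] &
    o$other_allele == ins$other_allele[has]
  swapped <- o$effect_allele == ins$other_allele[has] &
    o$other_allele == ins$effect_allele[has]

  action[has[pal]] <- "dropped_palindromic"
  ks <- has[!pal & same]
  kf <- has[!pal & swapped]
  action[has[!pal & !same & !swapped]] <- "dropped_mismatch"
  action[ks] <- "kept_same"
  action[kf] <- "kept_flipped"

  m <- match(ins$snp_id, out$snp_id)
  beta_out[ks] <- out$beta[m[ks]]
  se_out[ks] <- out$se[m[ks]]
  eaf_out[ks] <- out$eaf[m[ks]]
  beta_out[kf] <- -out$beta[m[kf]]
  se_out[kf] <- out$se[m[kf]]
  eaf_out[kf] <- 1 - out$eaf[m[kf]]

  audit <- data.frame(snp_id = ins$snp_id, action = action,
                      stringsAsFactors = FALSE)
  kept <- action %in% c("kept_same", "kept_flipped")
  records <- data.frame(
    snp_id = ins$snp_id[kept],
    chrom = ins$chrom[kept], pos = ins$pos[kept],
    beta_exp = ins$beta[kept], se_exp = ins$se[kept],
    beta_out = beta_out[kept], se_out = se_out[kept],
    eaf_out = eaf_out[kept], action = action[kept],
    stringsAsFactors = FALSE)
  rownames(records) <- NULL
  if (nrow(records) == 0) {
    mr_abort("mr_harmonization_empty",
             sprintf("no usable SNPs after harmonizing %s against %s",
                     instruments$exposure_name, outcome$trait_name))
  }
  structure(
    list(exposure_name = instruments$exposure_name,
         outcome_name = outcome$trait_name,
         stratum = instruments$stratum %||% "all",
         direction = direction,
         outcome_type = outcome$trait_type,
         records = records, audit = audit),
    class = "harmonized_data")
}

#' @export
print.harmonized_data <- function(x, ...) {
  tab <- table(factor(x$audit$action, levels = HARMONIZE_ACTIONS))
  cat(sprintf("<harmonized_data> %s -> %s (%s, %s): %d SNPs kept\n",
              x$exposure_name, x$outcome_name, x$stratum, x$direction,
              nrow(x$records)))
  cat(paste(sprintf("  %s: %d", names(tab), tab), collapse = "\n"), "\n")
  invisible(x)
}
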