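# Batch orchestration: run the full select -> harmonize -> estimate ->
# sensitivity chain for one exposure/outcome pair, render the two-criterion
# robustness verdict, and iterate a manifest of pairs (both directions, all
# strata). Forward and reverse analyses of the same pair share no state:
# instruments are selected independently per direction.

#' Analysis configuration
#'
#' Thresholds and method settings shared by [run_pair()] and [run_study()].
#' Defaults: genome-wide significance 5e-8 with 5e-6 fallback when fewer
#' than 2 SNPs survive clumping, clumping at r^2 < 0.001 within 10,000 kb,
#' F > 10, 1000 bootstrap replicates for the weighted median, 1000 MR-PRESSO
#' simulations at outlier alpha 0.05.
#'
#' @param p_primary,p_fallback,post_clump_min,r2_max,window_kb,f_min See
#'   [select_instruments()].
#' @param n_boot Weighted-median bootstrap replicates.
#' @param n_sim MR-PRESSO simulated datasets.
#' @param outlier_alpha MR-PRESSO outlier threshold.
#' @param seed Integer seed for all stochastic components.
#' @return Object of class `mr_config`.
#' @export
mr_config <- function(p_primary = 5e-8, p_fallback = 5e-6, post_clump_min = 2,
                      r2_max = 0.001, window_kb = 10000, f_min = 10,
                      n_boot = 1000, n_sim = 1000, outlier_alpha = 0.05,
                      seed = 13) {
  structure(list(p_primary = p_primary, p_fallback = p_fallback,
                 post_clump_min = post_clump_min, r2_max = r2_max,
                 window_kb = window_kb, f_min = f_min, n_boot = n_boot,
                 n_sim = n_sim, outlier_alpha = outlier_alpha,
                 seed = as.integer(seed)),
            class = "mr_config")
}

#' Two-criterion robustness verdict
#'
#' A causal finding is called relatively robust when (a) the IVW analysis is
#' significant at p < 0.05 and (b) the causal estimates of all available
#' methods (IVW, MR-Egger, weighted median) share one direction. Methods
#' unavailable because of instrument-count preconditions are excluded from
#' the direction comparison and listed, so a reduced comparison is visible.
#'
#' @param estimates Data frame from [mr_all_methods()].
#' @return Object of class `mr_verdict`: `ivw_significant`,
#'   `directions_consistent`, `robust` (the conjunction), and
#'   `methods_compared`.
#' @export
robustness_verdict <- function(estimates) {
  ivw <- estimates[estimates$method == "ivw_re", , drop = FALSE]
  stopifnot(nrow(ivw) == 1)
  avail <- estimates[!is.na(estimates$beta), , drop = FALSE]
  ivw_significant <- !is.na(ivw$pval) && ivw$pval < 0.05
  signs <- sign(avail$beta)
  signs <- signs[signs != 0]
  directions_consistent <- length(unique(signs)) <= 1
  structure(
    list(ivw_significant = ivw_significant,
         directions_consistent = directions_consistent,
         robust = ivw_significant && directions_consistent,
         methods_compared = avail$method),
    class = "mr_verdict")
}

#' @export
print.mr_verdict <- function(x, ...) {
  cat(sprintf(
    "<mr_verdict> robust=%s (IVW significant: %s; directions consistent: %s; compared: %s)\n",
    x$robust, x$ivw_significant, x$directions_consistent,
    paste(x$methods_compared, collapse = ", ")))
  invisible(x)
}

#' Run one exposure-outcome MR analysis end to end
#'
#' Selection, harmonization, the three estimators, the sensitivity battery,
#' and the robustness verdict. Selection and harmonization failures (no
#' instruments even at the fallback threshold, nothing left after
#' harmonization) do not raise: they yield a `"not_estimable"` status with
#' the reason attached.
#'
#' @param exposure,outcome [summary_stats()] objects.
#' @param ld Optional LD matrix for clumping (see [clump()]).
#' @param config An [mr_config()].
#' @param direction `"forward"` or `"reverse"`.
#' @return Object of class `mr_pair_result`: `status` (`"ok"` or
#'   `"not_estimable"`), `reason`, `estimates` (data frame), `sensitivity`,
#'   `verdict`, `instruments`, `harmonized`, plus the pair labels.
#' @export
run_pair <- function(exposure, outcome, ld = NULL, config = mr_config(),
                     direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  labels <- list(exposure = exposure$trait_name, outcome = outcome$trait_name,
                 stratum = exposure$stratum %||% "all", direction = direction)
  fail <- function(e) {
    structure(c(labels,
                list(status = "not_estimable", reason = conditionMessage(e),
                     estimates = NULL, sensitivity = NULL, verdict = NULL,
                     instruments = NULL, harmonized = NULL)),
              class = "mr_pair_result")
  }
  tryCatch({
    inst <- select_instruments(
      exposure, ld = ld, p_primary = config$p_primary,
      p_fallback = config$p_fallback, post_clump_min = config$post_clump_min,
      r2_max = config$r2_max, window_kb = config$window_kb,
      f_min = config$f_min)
    harm <- harmonize_pair(inst, outcome, direction = direction)
    estimates <- mr_all_methods(harm, n_boot = config$n_boot,
                                seed = config$seed)
    ivw <- mr_ivw(harm)
    sens <- run_sensitivity(harm, ivw = ivw, n_sim = config$n_sim,
                            outlier_alpha = config$outlier_alpha,
                            seed = config$seed + 1L)
    verdict <- robustness_verdict(estimates)
    structure(c(labels,
                list(status = "ok", reason = NA_character_,
                     estimates = estimates, sensitivity = sens,
                     verdict = verdict, instruments = inst,
                     harmonized = harm)),
              class = "mr_pair_result")
  }, mr_no_instruments = fail, mr_harmonization_empty = fail)
}

#' @export
print.mr_pair_result <- function(x, ...) {
  cat(sprintf("<mr_pair_result> %s -> %s (%s, %s): %s\n", x$exposure,
              x$outcome, x$stratum, x$direction, x$status))
  if (x$status == "ok") {
    print(x$estimates[, c("method", "n_snp", "beta", "se", "pval")],
          row.names = FALSE)
    print(x$verdict)
  } else {
    cat("  reason:", x$reason, "\n")
  }
  invisible(x)
}

#' Build a study manifest
#'
#' A manifest is the full grid of analyses to run: each entry names an
#' exposure table, an outcome table, the stratum and the direction. Entries
#' may hold in-memory [summary_stats()] objects or file paths (read lazily
#' with the default column map). Duplicate
#' (exposure, outcome, stratum, direction) combinations are rejected.
#'
#' @param pairs List of entries; each a list with `exposure`, `outcome`
#'   (`summary_stats` or path), optional `ld` (matrix or path), optional
#'   `exposure_name`, `outcome_name`, `exposure_type`, `outcome_type`,
#'   `stratum`, `direction`.
#' @param config Shared [mr_config()].
#' @return Object of class `study_manifest`.
#' @export
study_manifest <- function(pairs, config = mr_config()) {
  stopifnot(is.list(pairs), length(pairs) > 0)
  load_side <- function(x, name, type, stratum) {
    if (inherits(x, "summary_stats")) return(x)
    read_sumstats(x, trait_name = name %||% basename(x),
                  trait_type = type %||% "continuous",
                  stratum = stratum %||% "all")
  }
  pairs <- lapply(pairs, function(p) {
    p$direction <- p$direction %||% "forward"
    p$stratum <- p$stratum %||% "all"
    p$exposure <- load_side(p$exposure, p$exposure_name, p$exposure_type,
                            p$stratum)
    p$outcome <- load_side(p$outcome, p$outcome_name, p$outcome_type,
                           p$stratum)
    if (is.character(p$ld)) p$ld <- read_ld_matrix(p$ld)
    p
  })
  key <- vapply(pairs, function(p) {
    paste(p$exposure$trait_name, p$outcome$trait_name, p$stratum,
          p$direction, sep = "|")
  }, character(1))
  if (anyDuplicated(key)) {
    mr_abort("mr_config_error",
             sprintf("duplicate manifest entries: %s",
                     paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  structure(list(pairs = pairs, config = config), class = "study_manifest")
}

#' Run every analysis in a manifest
#'
#' Iterates the manifest's pairs, isolating failures: a pair that is not
#' estimable contributes a `"not estimable"` row to the combined table
#' instead of stopping the study. When `out_dir` is given, the combined
#' results table and one sensitivity JSON per estimable pair are written
#' there.
#'
#' @param manifest A [study_manifest()].
#' @param out_dir Optional output directory.
#' @param quiet Suppress per-pair progress messages.
#' @return Object of class `mr_study`: `results` (combined table, see
#'   [results_table()]), `pairs` (list of `mr_pair_result`), `robust`
#'   (subset of results rows from robust IVW findings).
#' @export
run_study <- function(manifest, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(manifest, "study_manifest"))
  results <- vector("list", length(manifest$pairs))
  for (i in seq_along(manifest$pairs)) {
    p <- manifest$pairs[[i]]
    if (!quiet) {
      message(sprintf("[%d/%d] %s -> %s (%s, %s)", i,
                      length(manifest$pairs), p$exposure$trait_name,
                      p$outcome$trait_name, p$stratum, p$direction))
    }
    results[[i]] <- run_pair(p$exposure, p$outcome, ld = p$ld,
                             config = manifest$config,
                             direction = p$direction)
  }
  tab <- results_table(results)
  robust <- tab[tab$robust_flag %in% TRUE & tab$method == "ivw_re", ,
                drop = FALSE]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_table(tab, file.path(out_dir, "mr_results.tsv"))
    for (r in results) {
      if (r$status == "ok") {
        fn <- sprintf("sensitivity_%s_%s_%s_%s.json", r$exposure, r$outcome,
                      r$stratum, r$direction)
        write_sensitivity_json(r$sensitivity, file.path(out_dir, fn))
      }
    }
  }
  structure(list(results = tab, pairs = results, robust = robust),
            class = "mr_study")
}

#' @export
print.mr_study <- function(x, ...) {
  cat(sprintf("<mr_study> %d analyses, %d robust finding(s)\n",
              length(x$pairs), nrow(x$robust)))
  if (nrow(x$robust) > 0) {
    print(x$robust[, c("exposure", "outcome", "stratum", "direction",
                       "n_snp", "beta", "pval")], row.names = FALSE)
  }
  invisible(x)
}

#' Combine pair results into the reporting table
#'
#' One row per (exposure, outcome, stratum, direction, method). For binary
#' outcomes, `ci_low`/`ci_high` hold the odds-ratio CI; for continuous
#' outcomes the beta CI and `or_` is `NA`. Pairs that were not estimable
#' contribute a single row with `method = NA` and empty estimates.
#'
#' @param pair_results List of [run_pair()] results (or a single one).
#' @return Data frame ready for [write_results_table()].
#' @export
results_table <- function(pair_results) {
  if (inherits(pair_results, "mr_pair_result")) {
    pair_results <- list(pair_results)
  }
  rows <- lapply(pair_results, function(r) {
    if (r$status != "ok") {
      return(data.frame(
        exposure = r$exposure, outcome = r$outcome, stratum = r$stratum,
        direction = r$direction, method = NA_character_, n_snp = NA_integer_,
        beta = NA_real_, se = NA_real_, or_ = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, pval = NA_real_, robust_flag = NA,
        note = r$reason, stringsAsFactors = FALSE))
    }
    e <- r$estimates
    binary <- !is.na(e$or_)
    data.frame(
      exposure = r$exposure, outcome = r$outcome, stratum = r$stratum,
      direction = r$direction, method = e$method, n_snp = e$n_snp,
      beta = e$beta, se = e$se, or_ = e$or_,
      ci_low = ifelse(binary, e$or_ci_low, e$ci_low),
      ci_high = ifelse(binary, e$or_ci_high, e$ci_high),
      pval = e$pval, robust_flag = r$verdict$robust,
      note = e$note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a study manifest from YAML
#'
#' Expected layout: a `config` mapping of [mr_config()] fields (all
#' optional) and a `pairs` sequence whose entries give `exposure`/`outcome`
#' file paths plus the optional fields of [study_manifest()].
#'
#' @param path Path to the YAML file. Relative data paths are resolved
#'   against the YAML file's directory.
#' @return A [study_manifest()].
#' @export
read_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$pairs)) {
    mr_abort("mr_config_error", "manifest has no 'pairs' section")
  }
  cfg <- do.call(mr_config, y$config %||% list())
  base <- dirname(normalizePath(path))
  resolve <- function(f) {
    if (is.null(f) || file.exists(f)) f else file.path(base, f)
  }
  pairs <- lapply(y$pairs, function(p) {
    p$exposure <- resolve(p$exposure)
    p$outcome <- resolve(p$outcome)
    p$ld <- resolve(p$ld)
    p
  })
  study_manifest(pairs, config = cfg)
}
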