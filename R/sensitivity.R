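# Sensitivity battery: Cochran's Q heterogeneity test over Wald ratios, the
# MR-Egger intercept test for directional pleiotropy, and MR-PRESSO (global
# residual-sum-of-squares test, per-SNP outlier test with Bonferroni
# correction, outlier-corrected estimate, and distortion test). Heterogeneity
# never auto-invalidates a result here: the random-effects IVW absorbs it,
# and the report only annotates.

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum_j v_j (theta_j - beta)^2 over per-SNP Wald ratios theta_j with
#' first-order inverse-variance weights v_j = (se_out,j / |beta_exp,j|)^-2,
#' referred to a chi-square with n-1 degrees of freedom. This is identical
#' to the weighted residual sum of squares about the IVW slope, and equals
#' (n-1) times the dispersion used by the random-effects IVW.
#'
#' @param data A [harmonize_pair()] result with at least 2 SNPs.
#' @param ivw_beta Pooled slope to measure dispersion around; defaults to
#'   the fixed-effect IVW slope of `data`.
#' @return List with `q_stat`, `q_df`, `q_pval`.
#' @export
cochrans_q <- function(data, ivw_beta = NULL) {
  v <- harm_vectors(data)
  k <- length(v$bx)
  if (k < 2) {
    mr_abort("mr_insufficient_instruments",
             sprintf("Cochran's Q needs >= 2 SNPs, got %d", k))
  }
  w <- 1 / v$sy^2
  if (is.null(ivw_beta)) ivw_beta <- ivw_core(v$bx, v$by, w)$beta
  vj <- (v$bx / v$sy)^2
  theta <- v$by / v$bx
  q <- sum(vj * (theta - ivw_beta)^2)
  list(q_stat = q, q_df = k - 1L,
       q_pval = stats::pchisq(q, df = k - 1, lower.tail = FALSE))
}

#' MR-Egger intercept test
#'
#' Two-sided normal p-value for intercept / intercept_se. A small p signals
#' directional horizontal pleiotropy; p > 0.05 is read as the intercept
#' being centred at the origin.
#'
#' @param intercept,intercept_se Intercept estimate and SE from [mr_egger()].
#' @return The p-value.
#' @export
egger_intercept_test <- function(intercept, intercept_se) {
  if (any(intercept_se <= 0)) {
    mr_abort("mr_domain_error", "intercept_se must be positive")
  }
  z_pvalue(intercept / intercept_se)
}

# leave-one-out fixed-effect IVW slopes and the weighted residuals used by
# MR-PRESSO; works column-wise over matrices for the simulated datasets
presso_loo_rss <- function(bx, by, w) {
  wxy <- w * bx * by
  wxx <- w * bx^2
  th_loo <- (sum(wxy) - wxy) / (sum(wxx) - wxx)
  res <- w * (by - th_loo * bx)^2
  list(th_loo = th_loo, res = res, rss = sum(res))
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' The observed residual sum of squares is computed with leave-one-out IVW
#' slopes: RSS = sum_j w_j (beta_out,j - theta_(-j) beta_exp,j)^2 with
#' w_j = 1/se_out,j^2. Its null distribution is simulated by drawing, for
#' each of `n_sim` datasets, outcome betas around theta_(-j) beta_exp,j with
#' SD se_out,j and exposure betas around beta_exp,j with SD se_exp,j, and
#' recomputing the leave-one-out RSS. Monte-Carlo p-values use the
#' (1 + exceedances)/(n_sim + 1) convention, so they are never exactly zero.
#' Per-SNP outlier p-values compare each observed weighted residual to its
#' simulated counterparts and are Bonferroni-multiplied by the SNP count;
#' SNPs below `outlier_alpha` are outliers. When outliers are found (but not
#' all SNPs), the outlier-corrected estimate is the random-effects IVW on
#' the remaining SNPs, and the distortion coefficient
#' 100 (theta_corrected - theta_all) / |theta_all| is referred to the
#' distribution obtained by removing equally many SNPs uniformly at random.
#'
#' @param data A [harmonize_pair()] result with at least 4 SNPs.
#' @param n_sim Number of simulated datasets.
#' @param outlier_alpha Significance threshold for Bonferroni-corrected
#'   per-SNP outlier p-values.
#' @param seed Integer seed.
#' @return List with `global_pval`, `rss_obs`, `outlier_pvals` (data frame:
#'   `snp_id`, `pval`), `outliers` (character vector), `corrected` (an
#'   `mr_estimate`, or `NULL` when no or all SNPs are outliers),
#'   `distortion_coef`, `distortion_pval` (both `NULL` without outliers),
#'   `n_sim`, `note`.
#' @export
mr_presso <- function(data, n_sim = 1000, outlier_alpha = 0.05, seed = 1) {
  v <- harm_vectors(data)
  k <- length(v$bx)
  if (k < 4) {
    mr_abort("mr_insufficient_instruments",
             sprintf("MR-PRESSO needs >= 4 SNPs, got %d", k))
  }
  # canonical SNP order so simulated noise attaches to SNPs by identifier:
  # all Monte-Carlo p-values are then invariant to input row order
  ord <- order(v$snp_id)
  v <- lapply(v, function(x) if (length(x) == k) x[ord] else x)
  w <- 1 / v$sy^2
  obs <- presso_loo_rss(v$bx, v$by, w)

  sim <- withr::with_seed(seed, {
    bx_s <- matrix(stats::rnorm(k * n_sim, v$bx, v$sx), nrow = k)
    by_s <- matrix(stats::rnorm(k * n_sim, obs$th_loo * v$bx, v$sy), nrow = k)
    wxy <- w * bx_s * by_s
    wxx <- w * bx_s^2
    th_loo_s <- (rep(colSums(wxy), each = k) - wxy) /
      (rep(colSums(wxx), each = k) - wxx)
    res_s <- w * (by_s - th_loo_s * bx_s)^2
    list(res = res_s, rss = colSums(res_s))
  })

  global_pval <- (1 + sum(sim$rss >= obs$rss)) / (n_sim + 1)
  p_raw <- (1 + rowSums(sim$res >= obs$res)) / (n_sim + 1)
  p_out <- pmin(1, p_raw * k)
  outliers <- v$snp_id[p_out < outlier_alpha]

  corrected <- NULL
  distortion_coef <- NULL
  distortion_pval <- NULL
  note <- NULL
  if (length(outliers) == k) {
    note <- "all SNPs flagged as outliers; corrected estimate unavailable"
  } else if (length(outliers) > 0) {
    sub <- data
    sub$records <- data$records[!(data$records$snp_id %in% outliers), ,
                                drop = FALSE]
    corrected <- mr_ivw(sub)
    beta_all <- ivw_core(v$bx, v$by, w)$beta
    distortion_coef <- 100 * (corrected$beta - beta_all) / abs(beta_all)
    n_rm <- length(outliers)
    d_null <- withr::with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(i) {
        drop <- sample.int(k, n_rm)
        b <- ivw_core(v$bx[-drop], v$by[-drop], w[-drop])$beta
        100 * (b - beta_all) / abs(beta_all)
      }, numeric(1))
    })
    distortion_pval <- (1 + sum(abs(d_null) >= abs(distortion_coef))) /
      (n_sim + 1)
  }

  list(global_pval = global_pval, rss_obs = obs$rss,
       outlier_pvals = data.frame(snp_id = v$snp_id, pval = p_out,
                                  stringsAsFactors = FALSE),
       outliers = outliers, corrected = corrected,
       distortion_coef = distortion_coef, distortion_pval = distortion_pval,
       n_sim = n_sim, note = note)
}

#' Assemble the full sensitivity report
#'
#' Runs Cochran's Q (>= 2 SNPs), the MR-Egger intercept test (>= 3 SNPs) and
#' MR-PRESSO (>= 4 SNPs), marking each component unavailable, with the
#' reason, when its instrument-count precondition fails.
#'
#' @param data A [harmonize_pair()] result.
#' @param ivw An `mr_estimate` from [mr_ivw()]; computed if `NULL`.
#' @param n_sim,outlier_alpha,seed Passed to [mr_presso()].
#' @return Object of class `sensitivity_report` with elements `n_snp`, `q`
#'   (`q_stat`, `q_df`, `q_pval`), `egger_intercept` (`estimate`, `se`,
#'   `pval`), `presso` (see [mr_presso()]) and `unavailable` (named list of
#'   reasons for skipped components).
#' @export
run_sensitivity <- function(data, ivw = NULL, n_sim = 1000,
                            outlier_alpha = 0.05, seed = 1) {
  stopifnot(inherits(data, "harmonized_data"))
  if (is.null(ivw)) ivw <- mr_ivw(data)
  k <- nrow(data$records)
  unavailable <- list()

  q <- NULL
  if (k >= 2) {
    q <- cochrans_q(data, ivw_beta = ivw$beta)
  } else {
    unavailable$q <- "fewer than 2 instruments"
  }
  egger_intercept <- NULL
  if (k >= 3) {
    egger_intercept <- mr_egger(data)$intercept
  } else {
    unavailable$egger_intercept <- "fewer than 3 instruments"
  }
  presso <- NULL
  if (k >= 4) {
    presso <- mr_presso(data, n_sim = n_sim, outlier_alpha = outlier_alpha,
                        seed = seed)
  } else {
    unavailable$presso <- "fewer than 4 instruments"
  }
  structure(
    list(n_snp = k, q = q, egger_intercept = egger_intercept,
         presso = presso, unavailable = unavailable),
    class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> %d SNPs\n", x$n_snp))
  if (!is.null(x$q)) {
    cat(sprintf("  Cochran's Q = %.3f (df %d), p = %.4g\n",
                x$q$q_stat, x$q$q_df, x$q$q_pval))
  }
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  Egger intercept = %.4f (se %.4f), p = %.4g\n",
                x$egger_intercept$estimate, x$egger_intercept$se,
                x$egger_intercept$pval))
  }
  if (!is.null(x$presso)) {
    cat(sprintf("  MR-PRESSO global p = %.4g; %d outlier(s)\n",
                x$presso$global_pval, length(x$presso$outliers)))
    if (!is.null(x$presso$distortion_pval)) {
      cat(sprintf("  distortion %.1f%%, p = %.4g\n",
                  x$presso$distortion_coef, x$presso$distortion_pval))
    }
  }
  for (nm in names(x$unavailable)) {
    cat(sprintf("  %s unavailable: %s\n", nm, x$unavailable[[nm]]))
  }
  invisible(x)
}

#' Serialize a sensitivity report to JSON
#'
#' @param report A [run_sensitivity()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_json <- function(report, path) {
  stopifnot(inherits(report, "sensitivity_report"))
  out <- list(
    n_snp = report$n_snp,
    q_stat = report$q$q_stat, q_df = report$q$q_df,
    q_pval = report$q$q_pval,
    egger_intercept = report$egger_intercept$estimate,
    egger_intercept_se = report$egger_intercept$se,
    egger_intercept_pval = report$egger_intercept$pval,
    presso_global_pval = report$presso$global_pval,
    presso_outliers = report$presso$outliers,
    presso_corrected_beta = report$presso$corrected$beta,
    presso_corrected_se = report$presso$corrected$se,
    presso_corrected_pval = report$presso$corrected$pval,
    presso_distortion_coef = report$presso$distortion_coef,
    presso_distortion_pval = report$presso$distortion_pval,
    n_sim = report$presso$n_sim,
    unavailable = report$unavailable
  )
  out <- out[!vapply(out, is.null, logical(1))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
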