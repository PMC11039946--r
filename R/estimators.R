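# The three causal estimators: multiplicative random-effects IVW (primary),
# MR-Egger regression, and the weighted median of Wald ratios with a
# parametric-bootstrap SE. All inference is z-based; the random-effects
# flavor is multiplicative with the dispersion floored at 1, so a reported
# SE is never below the fixed-effect SE.

new_mr_estimate <- function(method, n_snp, beta, se, binary, note = NULL) {
  ci_low <- beta - Z975 * se
  ci_high <- beta + Z975 * se
  est <- list(method = method, n_snp = as.integer(n_snp),
              beta = beta, se = se, ci_low = ci_low, ci_high = ci_high,
              pval = z_pvalue(beta / se),
              or_ = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
              note = note)
  if (isTRUE(binary)) {
    est$or_ <- exp(beta)
    est$or_ci_low <- exp(ci_low)
    est$or_ci_high <- exp(ci_high)
  }
  structure(est, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s (%d SNPs): beta=%.4f se=%.4f p=%.4g\n",
              x$method, x$n_snp, x$beta, x$se, x$pval))
  if (!is.na(x$or_)) {
    cat(sprintf("  OR=%.3f (%.3f, %.3f)\n", x$or_, x$or_ci_low, x$or_ci_high))
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

harm_vectors <- function(data) {
  stopifnot(inherits(data, "harmonized_data"))
  r <- data$records
  list(bx = r$beta_exp, sx = r$se_exp, by = r$beta_out, sy = r$se_out,
       snp_id = r$snp_id, binary = identical(data$outcome_type, "binary"))
}

#' Wald ratio for a single SNP
#'
#' beta = beta_out / beta_exp, with the first-order SE
#' se_out / |beta_exp| (exposure-side uncertainty ignored).
#'
#' @param beta_exp,se_exp Exposure association and SE.
#' @param beta_out,se_out Outcome association and SE.
#' @param binary Whether the outcome is binary (adds odds-ratio fields).
#' @return An `mr_estimate` with method `"wald_ratio"`.
#' @export
mr_wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                          binary = FALSE) {
  if (beta_exp == 0) {
    mr_abort("mr_domain_error", "Wald ratio undefined for beta_exp = 0")
  }
  new_mr_estimate("wald_ratio", 1L, beta_out / beta_exp,
                  se_out / abs(beta_exp), binary)
}

ivw_core <- function(bx, by, w) {
  sxx <- sum(w * bx^2)
  if (sxx == 0) {
    mr_abort("mr_domain_error", "all exposure betas are zero")
  }
  beta <- sum(w * bx * by) / sxx
  list(beta = beta, se_fixed = sqrt(1 / sxx),
       q = sum(w * (by - beta * bx)^2))
}

#' Inverse-variance weighted estimate (multiplicative random effects)
#'
#' Weighted least squares of outcome betas on exposure betas through the
#' origin with weights 1/se_out^2. The residual dispersion Q/(n-1) (Q is
#' Cochran's Q over the Wald ratios) multiplies the fixed-effect SE when it
#' exceeds 1, and is floored at 1 otherwise, so heterogeneity can only widen
#' the interval. With a single SNP the estimate degrades to the Wald ratio
#' and says so in its `note`.
#'
#' @param data A [harmonize_pair()] result.
#' @return An `mr_estimate` with method `"ivw_re"` (or `"wald_ratio"` when
#'   only one SNP is available).
#' @export
mr_ivw <- function(data) {
  v <- harm_vectors(data)
  k <- length(v$bx)
  if (k == 0) mr_abort("mr_domain_error", "no SNPs to estimate from")
  if (k == 1) {
    est <- mr_wald_ratio(v$bx, v$sx, v$by, v$sy, binary = v$binary)
    est$note <- "single instrument: IVW degraded to Wald ratio"
    return(est)
  }
  fit <- ivw_core(v$bx, v$by, 1 / v$sy^2)
  dispersion <- fit$q / (k - 1)
  se <- fit$se_fixed * max(1, sqrt(dispersion))
  new_mr_estimate("ivw_re", k, fit$beta, se, v$binary)
}

#' MR-Egger regression
#'
#' Each SNP is first oriented so its exposure beta is nonnegative (both betas
#' flipped together), then outcome betas are regressed on exposure betas with
#' an unconstrained intercept, weights 1/se_out^2. The slope is a
#' pleiotropy-adjusted causal estimate; the intercept estimates the average
#' directional pleiotropic effect, and its two-sided z test is the standard
#' pleiotropy check. SEs of both coefficients carry the same multiplicative
#' dispersion (weighted residual mean square on n-2 df) floored at 1.
#'
#' @param data A [harmonize_pair()] result with at least 3 SNPs.
#' @return List with `slope` (an `mr_estimate`, method `"egger"`) and
#'   `intercept` (list: `estimate`, `se`, `pval`).
#' @export
mr_egger <- function(data) {
  v <- harm_vectors(data)
  k <- length(v$bx)
  if (k < 3) {
    mr_abort("mr_insufficient_instruments",
             sprintf("MR-Egger needs >= 3 SNPs, got %d", k))
  }
  flip <- sign(v$bx)
  flip[flip == 0] <- 1
  bx <- v$bx * flip
  by <- v$by * flip
  w <- 1 / v$sy^2

  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  if (det <= 0) {
    mr_abort("mr_domain_error", "degenerate design in MR-Egger regression")
  }
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- by - intercept - slope * bx
  dispersion <- sum(w * resid^2) / (k - 2)
  infl <- max(1, sqrt(dispersion))
  se_slope <- sqrt(sw / det) * infl
  se_intercept <- sqrt(swxx / det) * infl

  list(
    slope = new_mr_estimate("egger", k, slope, se_slope, v$binary),
    intercept = list(estimate = intercept, se = se_intercept,
                     pval = z_pvalue(intercept / se_intercept))
  )
}

# weighted median of `x` with weights `w`: normalize, sort, and linearly
# interpolate the weighted CDF (evaluated at cumsum(w) - w/2) at 0.5
weighted_median_point <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(x[1])
  k <- length(x)
  if (s[k] < 0.5) return(x[k])
  i <- max(which(s < 0.5))
  x[i] + (x[i + 1] - x[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
}

#' Weighted-median causal estimate
#'
#' Per-SNP Wald ratios weighted by the inverse variance of the ratio
#' (first-order: w_j = (se_out,j / beta_exp,j)^-2). Consistent when at least
#' half the total weight comes from valid instruments. The SE is a
#' parametric bootstrap: exposure and outcome betas are resampled from
#' normal distributions centred on their estimates with their reported SEs,
#' the weighted median recomputed, and the SD over `n_boot` replicates
#' reported.
#'
#' @param data A [harmonize_pair()] result with at least 3 SNPs.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed for the bootstrap (required for reproducibility).
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = 1) {
  v <- harm_vectors(data)
  k <- length(v$bx)
  if (k < 3) {
    mr_abort("mr_insufficient_instruments",
             sprintf("weighted median needs >= 3 SNPs, got %d", k))
  }
  # canonical SNP order: bootstrap draws attach to SNPs by identifier, so
  # the estimate and SE are invariant to input row order under a fixed seed
  ord <- order(v$snp_id)
  v <- lapply(v, function(x) if (length(x) == k) x[ord] else x)
  ratio <- v$by / v$bx
  w <- (v$bx / v$sy)^2
  beta <- weighted_median_point(ratio, w)
  boots <- withr::with_seed(seed, {
    bx_b <- matrix(stats::rnorm(k * n_boot, v$bx, v$sx), nrow = k)
    by_b <- matrix(stats::rnorm(k * n_boot, v$by, v$sy), nrow = k)
    vapply(seq_len(n_boot), function(j) {
      weighted_median_point(by_b[, j] / bx_b[, j], (bx_b[, j] / v$sy)^2)
    }, numeric(1))
  })
  new_mr_estimate("weighted_median", k, beta, stats::sd(boots), v$binary)
}

#' Convert a causal estimate to the reporting scale
#'
#' For binary outcomes: OR = exp(beta) with 95% CI exp(beta +/- 1.96 se);
#' for continuous outcomes the beta-scale CI is reported and `or_` is `NA`.
#' The p-value is the two-sided normal p for beta/se in both cases.
#'
#' @param beta,se Estimate and SE on the log-odds (binary) or linear scale.
#' @param binary_outcome Logical.
#' @return List with `or_`, `ci_low`, `ci_high`, `pval`.
#' @export
estimate_to_summary <- function(beta, se, binary_outcome = TRUE) {
  if (any(se <= 0)) mr_abort("mr_domain_error", "se must be positive")
  lo <- beta - Z975 * se
  hi <- beta + Z975 * se
  if (binary_outcome) {
    list(or_ = exp(beta), ci_low = exp(lo), ci_high = exp(hi),
         pval = z_pvalue(beta / se))
  } else {
    list(or_ = NA_real_, ci_low = lo, ci_high = hi,
         pval = z_pvalue(beta / se))
  }
}

#' Run all applicable estimators on a harmonized dataset
#'
#' IVW always runs (degrading to the Wald ratio at one SNP); MR-Egger and
#' the weighted median require at least 3 SNPs and are skipped, with a note,
#' below that.
#'
#' @inheritParams mr_weighted_median
#' @return Data frame with one row per attempted method: `method`, `n_snp`,
#'   `beta`, `se`, `ci_low`, `ci_high` (beta scale), `pval`, `or_`,
#'   `or_ci_low`, `or_ci_high`, `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_pval`, `note`.
#' @export
mr_all_methods <- function(data, n_boot = 1000, seed = 1) {
  est_row <- function(e, note = NA_character_, method = NULL) {
    if (is.null(e)) {
      return(data.frame(method = method, n_snp = nrow(data$records),
                        beta = NA_real_, se = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, pval = NA_real_, or_ = NA_real_,
                        or_ci_low = NA_real_, or_ci_high = NA_real_,
                        egger_intercept = NA_real_,
                        egger_intercept_se = NA_real_,
                        egger_intercept_pval = NA_real_,
                        note = note, stringsAsFactors = FALSE))
    }
    data.frame(method = method %||% e$method, n_snp = e$n_snp, beta = e$beta,
               se = e$se, ci_low = e$ci_low, ci_high = e$ci_high,
               pval = e$pval, or_ = e$or_, or_ci_low = e$or_ci_low,
               or_ci_high = e$or_ci_high,
               egger_intercept = NA_real_, egger_intercept_se = NA_real_,
               egger_intercept_pval = NA_real_,
               note = e$note %||% note, stringsAsFactors = FALSE)
  }
  rows <- list(est_row(mr_ivw(data), method = "ivw_re"))
  eg <- tryCatch(mr_egger(data), mr_insufficient_instruments = function(e) e)
  if (inherits(eg, "condition")) {
    rows$egger <- est_row(NULL, note = conditionMessage(eg), method = "egger")
  } else {
    r <- est_row(eg$slope, method = "egger")
    r$egger_intercept <- eg$intercept$estimate
    r$egger_intercept_se <- eg$intercept$se
    r$egger_intercept_pval <- eg$intercept$pval
    rows$egger <- r
  }
  wm <- tryCatch(mr_weighted_median(data, n_boot = n_boot, seed = seed),
                 mr_insufficient_instruments = function(e) e)
  rows$wm <- if (inherits(wm, "condition")) {
    est_row(NULL, note = conditionMessage(wm), method = "weighted_median")
  } else {
    est_row(wm, method = "weighted_median")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
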