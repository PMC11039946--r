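# Generator of paired exposure/outcome GWAS summary statistics under a known
# structural model. Per SNP j with minor-allele frequency MAF_j:
#
#   gamma_j : true effect on the (standardized, continuous) exposure; a
#             null fraction of SNPs gets gamma_j = 0
#   se_exp,j = 1 / sqrt(2 * n_exp * MAF_j * (1 - MAF_j))
#   beta_exp,j ~ Normal(gamma_j, se_exp,j^2)
#   alpha_j : horizontal-pleiotropy effect, 0 for valid SNPs, else
#             Normal(mu_alpha, sigma_alpha^2)
#   se_out,j = 1 / sqrt(2 * n_out * MAF_j * (1 - MAF_j))
#   beta_out,j ~ Normal(theta * gamma_j + alpha_j, se_out,j^2)
#
# Exposure and outcome sampling errors are independent (the two-sample
# design). Within an LD block exposure errors share a constant pairwise
# correlation r and non-lead SNPs carry gamma scaled by r; a fraction of
# SNPs gets palindromic allele pairs, and a fraction of outcome rows is
# emitted with swapped alleles and negated beta to exercise harmonization.
#
# All random quantities are drawn unconditionally in a fixed order and masks
# are applied afterwards, so changing one fraction (e.g. frac_flipped 0 -> 1)
# leaves every other draw bit-identical under the same seed.

#' Configuration for the two-sample summary-statistics generator
#'
#' Defaults emulate a well-powered continuous exposure GWAS (hormone-scale,
#' n = 200,000) against a disease outcome GWAS of roughly the combined
#' case/control size of the IBD datasets (n = 35,000), with a candidate panel
#' of 2,000 SNPs of which 5% are true instruments.
#'
#' @param m Number of candidate SNPs.
#' @param theta True causal effect of the exposure on the outcome (log-odds
#'   per exposure SD).
#' @param n_exp,n_out Exposure / outcome GWAS sample sizes.
#' @param maf_range Interval within (0, 0.5] for uniform minor-allele
#'   frequencies; zero width allowed.
#' @param gamma_mean,gamma_sd Normal distribution of nonzero instrument
#'   effects.
#' @param gamma_null_frac Fraction of SNPs with no exposure effect.
#' @param pi_invalid Fraction of SNPs with horizontal pleiotropy.
#' @param mu_alpha,sigma_alpha Mean and SD of pleiotropic effects on the
#'   outcome.
#' @param ld_blocks List of `list(size =, r =)` entries; each creates one LD
#'   block of `size` SNPs with constant pairwise correlation `r` in `[0, 1]`
#'   among exposure sampling errors, non-lead members sharing `r * gamma` of
#'   the lead.
#' @param frac_palindromic Fraction of SNPs given A/T or C/G allele pairs.
#' @param frac_flipped Fraction of outcome rows emitted with swapped alleles,
#'   negated beta and complemented frequency.
#' @param seed Integer seed; with it fixed the output is bit-identical.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(m = 2000, theta = 0, n_exp = 2e5, n_out = 3.5e4,
                       maf_range = c(0.05, 0.5),
                       gamma_mean = 0.08, gamma_sd = 0.03,
                       gamma_null_frac = 0.95,
                       pi_invalid = 0, mu_alpha = 0, sigma_alpha = 0,
                       ld_blocks = list(),
                       frac_palindromic = 0.2, frac_flipped = 0.3,
                       seed = 1) {
  cfg <- list(m = as.integer(m), theta = theta, n_exp = n_exp, n_out = n_out,
              maf_range = maf_range, gamma_mean = gamma_mean,
              gamma_sd = gamma_sd, gamma_null_frac = gamma_null_frac,
              pi_invalid = pi_invalid, mu_alpha = mu_alpha,
              sigma_alpha = sigma_alpha, ld_blocks = ld_blocks,
              frac_palindromic = frac_palindromic,
              frac_flipped = frac_flipped, seed = as.integer(seed))
  stopifnot(cfg$m >= 1, cfg$n_exp >= 2, cfg$n_out >= 2)
  for (f in c("pi_invalid", "frac_palindromic", "frac_flipped",
              "gamma_null_frac")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      mr_abort("mr_config_error", sprintf("%s must lie in [0, 1]", f))
    }
  }
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    mr_abort("mr_config_error",
             "maf_range bounds must satisfy 0 < low <= high <= 0.5")
  }
  for (b in cfg$ld_blocks) {
    if (is.null(b$size) || is.null(b$r) || b$r < 0 || b$r > 1 || b$size < 2) {
      mr_abort("mr_config_error",
               "each ld_block needs size >= 2 and pairwise r in [0, 1]")
    }
  }
  if (sum(vapply(cfg$ld_blocks, `[[`, numeric(1), "size")) > cfg$m) {
    mr_abort("mr_config_error", "ld_blocks cannot cover more than m SNPs")
  }
  structure(cfg, class = "sim_config")
}

NONPALINDROMIC_PAIRS <- matrix(c("A","C", "A","G", "C","A", "C","T",
                                 "G","A", "G","T", "T","C", "T","G"),
                               ncol = 2, byrow = TRUE)
PALINDROMIC_PAIRS <- matrix(c("A","T", "T","A", "C","G", "G","C"),
                            ncol = 2, byrow = TRUE)

#' Simulate one paired exposure/outcome summary-statistics dataset
#'
#' @param config A [sim_config()] object.
#' @return A list of class `mr_simulation` with elements `exposure` and
#'   `outcome` (two [summary_stats()] objects over the same SNPs), `ld`
#'   (constant-correlation block LD matrix over the SNPs inside blocks, with
#'   SNP identifiers as dimnames; `NULL` when no blocks were requested) and
#'   `truth` (the generating parameters: `theta` and a per-SNP table of
#'   `maf`, `gamma`, `alpha`, `valid`, `block`). The truth record is never
#'   part of the emitted summary-statistics tables.
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_two_sample_impl(config))
}

simulate_two_sample_impl <- function(cfg) {
  m <- cfg$m
  snp_id <- sprintf("rs%d", 1000000 + seq_len(m))

  # block structure: blocks occupy the first SNPs, in the order given
  block <- rep(0L, m)
  block_r <- vapply(cfg$ld_blocks, `[[`, numeric(1), "r")
  pos_in_block <- rep(1L, m)
  i <- 1L
  for (b in seq_along(cfg$ld_blocks)) {
    size <- as.integer(cfg$ld_blocks[[b]]$size)
    block[i:(i + size - 1L)] <- b
    pos_in_block[i:(i + size - 1L)] <- seq_len(size)
    i <- i + size
  }

  # genomic coordinates: one locus per block or singleton, loci spaced
  # 25,000 kb apart (beyond any clumping window), block members 10 kb apart
  locus <- cumsum(pos_in_block == 1L)
  chrom <- as.character(((locus - 1L) %% 22L) + 1L)
  locus_on_chrom <- ((locus - 1L) %/% 22L) + 1L
  pos <- locus_on_chrom * 25e6 + (pos_in_block - 1L) * 1e4

  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  gamma_raw <- stats::rnorm(m, cfg$gamma_mean, cfg$gamma_sd)
  null_mask <- stats::runif(m) < cfg$gamma_null_frac
  gamma <- ifelse(null_mask, 0, gamma_raw)
  # block members inherit the lead SNP's gamma scaled by the block r
  for (b in seq_along(cfg$ld_blocks)) {
    idx <- which(block == b)
    lead <- idx[1]
    gamma[idx[-1]] <- block_r[b] * gamma[lead]
  }

  se_exp <- 1 / sqrt(2 * cfg$n_exp * maf * (1 - maf))
  se_out <- 1 / sqrt(2 * cfg$n_out * maf * (1 - maf))

  z_exp <- stats::rnorm(m)
  z_block <- stats::rnorm(max(1L, length(cfg$ld_blocks)))
  for (b in seq_along(cfg$ld_blocks)) {
    idx <- which(block == b)
    r <- block_r[b]
    z_exp[idx] <- sqrt(r) * z_block[b] + sqrt(1 - r) * z_exp[idx]
  }
  beta_exp <- gamma + se_exp * z_exp

  invalid <- stats::runif(m) < cfg$pi_invalid
  alpha_raw <- stats::rnorm(m, cfg$mu_alpha, cfg$sigma_alpha)
  alpha <- ifelse(invalid, alpha_raw, 0)
  beta_out <- cfg$theta * gamma + alpha + stats::rnorm(m, 0, se_out)

  pair_np <- NONPALINDROMIC_PAIRS[sample.int(8L, m, replace = TRUE), ,
                                  drop = FALSE]
  pair_pal <- PALINDROMIC_PAIRS[sample.int(4L, m, replace = TRUE), ,
                                drop = FALSE]
  pal_mask <- stats::runif(m) < cfg$frac_palindromic
  a1 <- ifelse(pal_mask, pair_pal[, 1], pair_np[, 1])
  a2 <- ifelse(pal_mask, pair_pal[, 2], pair_np[, 2])
  flip_mask <- stats::runif(m) < cfg$frac_flipped

  # two-sided normal p-values, clamped away from 0 so extreme associations
  # survive the 0 < p <= 1 validation invariant
  pclamp <- function(p) pmax(p, .Machine$double.xmin)
  exp_records <- data.frame(
    snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = a1, other_allele = a2, eaf = maf,
    beta = beta_exp, se = se_exp,
    pval = pclamp(z_pvalue(beta_exp / se_exp)), n = cfg$n_exp,
    stringsAsFactors = FALSE)
  out_records <- data.frame(
    snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = ifelse(flip_mask, a2, a1),
    other_allele = ifelse(flip_mask, a1, a2),
    eaf = ifelse(flip_mask, 1 - maf, maf),
    beta = ifelse(flip_mask, -beta_out, beta_out), se = se_out,
    pval = pclamp(z_pvalue(beta_out / se_out)), n = cfg$n_out,
    stringsAsFactors = FALSE)

  ld <- NULL
  if (length(cfg$ld_blocks) > 0) {
    in_block <- which(block > 0L)
    ld <- diag(length(in_block))
    for (b in seq_along(cfg$ld_blocks)) {
      j <- match(which(block == b), in_block)
      ld[j, j] <- block_r[b]
    }
    diag(ld) <- 1
    dimnames(ld) <- list(snp_id[in_block], snp_id[in_block])
  }

  truth <- list(
    theta = cfg$theta,
    snps = data.frame(snp_id = snp_id, maf = maf, gamma = gamma,
                      alpha = alpha, valid = !invalid, block = block,
                      stringsAsFactors = FALSE))

  structure(
    list(exposure = summary_stats(exp_records, "sim_exposure", "continuous"),
         outcome = summary_stats(out_records, "sim_outcome", "binary"),
         ld = ld, truth = truth, config = cfg),
    class = "mr_simulation")
}

#' @export
print.mr_simulation <- function(x, ...) {
  cat(sprintf("<mr_simulation> m=%d theta=%g seed=%d (%d LD block(s))\n",
              x$config$m, x$truth$theta, x$config$seed,
              length(x$config$ld_blocks)))
  invisible(x)
}

#' Run the full selection-harmonization-estimation chain over replicates
#'
#' Replicate i uses seed `config$seed + i - 1`. Each replicate simulates a
#' paired dataset, selects instruments, harmonizes, and applies the requested
#' estimator(s). Replicates where selection or harmonization leaves no usable
#' instrument (or too few for a method) are counted and skipped for that
#' method.
#'
#' @param config A [sim_config()]; its seed is the base seed.
#' @param n_reps Number of replicates (>= 1).
#' @param methods Character vector among `"ivw_re"`, `"egger"`,
#'   `"weighted_median"`.
#' @param alpha Significance level for the rejection count.
#' @param n_boot Bootstrap replicates for the weighted-median SE.
#' @param mr_cfg An [mr_config()] with the selection thresholds.
#' @return List of class `mr_replicates`: `summary` (one row per method with
#'   `rejection_rate` at `alpha`, `mean_estimate`, `sd_estimate`, `mean_se`,
#'   `n_used`, `n_skipped`) and `estimates` (per-replicate rows, including
#'   the MR-Egger intercept where applicable).
#' @export
simulate_replicates <- function(config, n_reps, methods = "ivw_re",
                                alpha = 0.05, n_boot = 1000,
                                mr_cfg = mr_config()) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  methods <- match.arg(methods, c("ivw_re", "egger", "weighted_median"),
                       several.ok = TRUE)
  rows <- vector("list", n_reps)
  n_failed <- 0L
  for (i in seq_len(n_reps)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    sim <- simulate_two_sample(cfg_i)
    harm <- tryCatch({
      inst <- select_instruments(
        sim$exposure, ld = sim$ld,
        p_primary = mr_cfg$p_primary, p_fallback = mr_cfg$p_fallback,
        post_clump_min = mr_cfg$post_clump_min, r2_max = mr_cfg$r2_max,
        window_kb = mr_cfg$window_kb, f_min = mr_cfg$f_min)
      harmonize_pair(inst, sim$outcome)
    }, mr_error = function(e) NULL)
    if (is.null(harm)) {
      n_failed <- n_failed + 1L
      next
    }
    k <- nrow(harm$records)
    rep_rows <- lapply(methods, function(mth) {
      est <- tryCatch(switch(
        mth,
        ivw_re = mr_ivw(harm),
        egger = mr_egger(harm),
        weighted_median = mr_weighted_median(harm, n_boot = n_boot,
                                             seed = cfg_i$seed + 500011L)
      ), mr_error = function(e) NULL)
      if (is.null(est)) {
        return(data.frame(method = mth, seed = cfg_i$seed, n_snp = k,
                          beta = NA_real_, se = NA_real_, pval = NA_real_,
                          intercept = NA_real_, intercept_pval = NA_real_))
      }
      if (mth == "egger") {
        data.frame(method = mth, seed = cfg_i$seed, n_snp = est$slope$n_snp,
                   beta = est$slope$beta, se = est$slope$se,
                   pval = est$slope$pval, intercept = est$intercept$estimate,
                   intercept_pval = est$intercept$pval)
      } else {
        data.frame(method = mth, seed = cfg_i$seed, n_snp = est$n_snp,
                   beta = est$beta, se = est$se, pval = est$pval,
                   intercept = NA_real_, intercept_pval = NA_real_)
      }
    })
    rows[[i]] <- do.call(rbind, rep_rows)
  }
  estimates <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(estimates)) {
    estimates <- data.frame(method = character(), seed = integer(),
                            n_snp = integer(), beta = numeric(),
                            se = numeric(), pval = numeric(),
                            intercept = numeric(),
                            intercept_pval = numeric())
  }
  summary <- do.call(rbind, lapply(methods, function(mth) {
    e <- estimates[estimates$method == mth & !is.na(estimates$beta), ,
                   drop = FALSE]
    data.frame(method = mth,
               rejection_rate = mean(e$pval < alpha),
               mean_estimate = mean(e$beta),
               sd_estimate = stats::sd(e$beta),
               mean_se = mean(e$se),
               mean_intercept = mean(e$intercept),
               n_used = nrow(e),
               n_skipped = n_reps - nrow(e))
  }))
  structure(list(summary = summary, estimates = estimates,
                 n_reps = n_reps, n_failed = n_failed, alpha = alpha),
            class = "mr_replicates")
}

#' @export
print.mr_replicates <- function(x, ...) {
  cat(sprintf("<mr_replicates> %d replicates (%d with no usable instruments)\n",
              x$n_reps, x$n_failed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits `<prefix>exposure.tsv`, `<prefix>outcome.tsv`, `<prefix>ld.tsv`
#' (square correlation matrix with a SNP header; only when LD blocks exist)
#' and `<prefix>truth.json`.
#'
#' @param sim An `mr_simulation` from [simulate_two_sample()].
#' @param prefix Path prefix, e.g. `"sim/"` or `"sim/run1_"`.
#' @return Character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  stopifnot(inherits(sim, "mr_simulation"))
  dir.create(dirname(paste0(prefix, "x")), recursive = TRUE,
             showWarnings = FALSE)
  files <- c(paste0(prefix, "exposure.tsv"), paste0(prefix, "outcome.tsv"))
  write_sumstats(sim$exposure, files[1])
  write_sumstats(sim$outcome, files[2])
  if (!is.null(sim$ld)) {
    f <- paste0(prefix, "ld.tsv")
    utils::write.table(data.frame(SNP = rownames(sim$ld), sim$ld,
                                  check.names = FALSE),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  f <- paste0(prefix, "truth.json")
  jsonlite::write_json(sim$truth, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}

#' Read an LD matrix written by [write_simulation()]
#' @param path Path to a tab-delimited square matrix whose first column (and
#'   header) hold SNP identifiers.
#' @return Numeric matrix with SNP dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  storage.mode(m) <- "double"
  m
}
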