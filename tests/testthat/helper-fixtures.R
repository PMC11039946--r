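# In-code fixtures shared across the suite. Everything is built
# programmatically; no data files.

# minimal well-formed summary-statistics data frame; override any column
make_records <- function(n = 5, ...) {
  out <- data.frame(
    snp_id = sprintf("rs%d", seq_len(n)),
    chrom = rep("1", n),
    pos = seq_len(n) * 1e6,
    effect_allele = rep("A", n),
    other_allele = rep("G", n),
    eaf = rep(0.3, n),
    beta = rep(0.1, n),
    se = rep(0.01, n),
    pval = rep(1e-9, n),
    n = rep(1e5, n),
    stringsAsFactors = FALSE)
  dots <- list(...)
  for (nm in names(dots)) out[[nm]] <- dots[[nm]]
  out
}

make_stats <- function(n = 5, trait_name = "X", trait_type = "continuous",
                       stratum = "all", ...) {
  summary_stats(make_records(n, ...), trait_name = trait_name,
                trait_type = trait_type, stratum = stratum)
}

# harmonized dataset built directly from effect vectors (unit-test entry
# point for the estimators and sensitivity battery)
make_harmonized <- function(bx, sx, by, sy, binary = TRUE,
                            snp_id = sprintf("rs%d", seq_along(bx))) {
  structure(
    list(exposure_name = "X", outcome_name = "Y", stratum = "all",
         direction = "forward",
         outcome_type = if (binary) "binary" else "continuous",
         records = data.frame(
           snp_id = snp_id, chrom = "1", pos = seq_along(bx) * 1e6,
           beta_exp = bx, se_exp = sx, beta_out = by, se_out = sy,
           eaf_out = 0.3, action = "kept_same", stringsAsFactors = FALSE),
         audit = data.frame(snp_id = snp_id, action = "kept_same",
                            stringsAsFactors = FALSE)),
    class = "harmonized_data")
}

# constant-correlation LD matrix over the given SNPs
make_ld <- function(snp_ids, r = 0) {
  m <- matrix(r, length(snp_ids), length(snp_ids),
              dimnames = list(snp_ids, snp_ids))
  diag(m) <- 1
  m
}

# independent weighted-quantile oracle: inverts the piecewise-linear
# weighted CDF by brute force over a fine probability grid
oracle_weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  cdf_at <- cumsum(w) - w / 2
  stats::approx(cdf_at, x, xout = 0.5, rule = 2)$y
}
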