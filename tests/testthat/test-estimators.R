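test_that("Wald ratio handles scale and sign and rejects a null exposure effect", {
  w <- mr_wald_ratio(0.2, 0.01, 0.06, 0.02)
  expect_equal(w$beta, 0.3)
  expect_equal(w$se, 0.1)
  expect_equal(mr_wald_ratio(-0.2, 0.01, 0.06, 0.02)$beta, -0.3)
  expect_equal(mr_wald_ratio(-0.2, 0.01, 0.06, 0.02)$se, 0.1)
  expect_equal(mr_wald_ratio(0.2, 0.01, 0, 0.02)$beta, 0)
  expect_error(mr_wald_ratio(0, 0.01, 0.06, 0.02), class = "mr_domain_error")
})

test_that("IVW matches a generic weighted regression through the origin", {
  bx <- c(0.08, 0.12, 0.05, 0.15, 0.10)
  by <- c(0.030, 0.020, 0.025, 0.060, 0.015)  # heterogeneous on purpose
  sy <- c(0.008, 0.010, 0.012, 0.009, 0.011)
  h <- make_harmonized(bx, 0.004, by, sy)
  est <- mr_ivw(h)
  fit <- stats::lm(by ~ 0 + bx, weights = 1 / sy^2)
  expect_equal(est$beta, unname(stats::coef(fit)), tolerance = 1e-10)
  # the multiplicative random-effects SE equals the sigma-scaled regression
  # SE whenever the dispersion exceeds 1 (it does here)
  expect_gt(summary(fit)$sigma, 1)
  expect_equal(est$se, unname(summary(fit)$coef[, "Std. Error"]),
               tolerance = 1e-10)
})

test_that("IVW floors the dispersion at the fixed-effect SE", {
  # k identical SNPs: same beta as one copy, base SE shrunk by sqrt(k),
  # zero dispersion -> floor applies
  one <- make_harmonized(0.1, 0.004, 0.03, 0.01)
  four <- make_harmonized(rep(0.1, 4), 0.004, rep(0.03, 4), 0.01)
  e1 <- mr_ivw(four)
  expect_equal(e1$beta, 0.3)
  expect_equal(e1$beta, mr_wald_ratio(0.1, 0.004, 0.03, 0.01)$beta)
  expect_equal(e1$se, (0.01 / 0.1) / sqrt(4))
  # single SNP degrades to the Wald ratio with a note
  d <- mr_ivw(one)
  expect_identical(d$method, "wald_ratio")
  expect_match(d$note, "single instrument")
})

test_that("MR-Egger matches a generic weighted regression with intercept", {
  bx <- c(0.06, 0.09, 0.12, 0.15)
  by <- c(0.050, 0.030, 0.065, 0.045)
  sy <- c(0.010, 0.008, 0.012, 0.009)
  h <- make_harmonized(bx, 0.004, by, sy)
  eg <- mr_egger(h)
  fit <- stats::lm(by ~ bx, weights = 1 / sy^2)
  expect_equal(eg$slope$beta, unname(stats::coef(fit)[2]), tolerance = 1e-10)
  expect_equal(eg$intercept$estimate, unname(stats::coef(fit)[1]),
               tolerance = 1e-10)
  expect_gt(summary(fit)$sigma, 1)
  se <- summary(fit)$coef[, "Std. Error"]
  expect_equal(eg$slope$se, unname(se[2]), tolerance = 1e-10)
  expect_equal(eg$intercept$se, unname(se[1]), tolerance = 1e-10)
})

test_that("MR-Egger orients exposure effects nonnegative before regressing", {
  bx <- c(0.06, -0.09, 0.12, -0.15)
  by <- c(0.050, -0.030, 0.065, -0.045)
  sy <- c(0.010, 0.008, 0.012, 0.009)
  eg <- mr_egger(make_harmonized(bx, 0.004, by, sy))
  fit <- stats::lm(I(sign(bx) * by) ~ I(abs(bx)), weights = 1 / sy^2)
  expect_equal(eg$slope$beta, unname(stats::coef(fit)[2]), tolerance = 1e-10)
})

test_that("data on an exact line through the origin give a zero Egger intercept", {
  bx <- c(0.05, 0.08, 0.11, 0.14)
  eg <- mr_egger(make_harmonized(bx, 0.004, 0.4 * bx, 0.01))
  expect_equal(eg$intercept$estimate, 0, tolerance = 1e-12)
  expect_equal(eg$slope$beta, 0.4, tolerance = 1e-12)
  expect_error(mr_egger(make_harmonized(bx[1:2], 0.004, bx[1:2], 0.01)),
               class = "mr_insufficient_instruments")
})

test_that("the weighted median interpolates the weighted CDF of Wald ratios", {
  # equal weights, ratios {0.1, 0.3, 0.9} -> 0.3
  est <- mr_weighted_median(make_harmonized(rep(1, 3), 0.001,
                                            c(0.1, 0.3, 0.9), 1),
                            n_boot = 50, seed = 1)
  expect_equal(est$beta, 0.3)
  # general case against the independent weighted-quantile oracle
  set.seed(5)
  for (i in 1:5) {
    bx <- stats::runif(7, 0.05, 0.2)
    by <- stats::rnorm(7, 0.3 * bx, 0.02)
    sy <- stats::runif(7, 0.008, 0.02)
    h <- make_harmonized(bx, 0.004, by, sy)
    est <- mr_weighted_median(h, n_boot = 10, seed = 1)
    expect_equal(est$beta,
                 oracle_weighted_median(by / bx, (bx / sy)^2),
                 tolerance = 1e-10)
  }
  # equal weights and odd n: the plain sample median
  ratios <- c(0.12, 0.4, 0.22, 0.31, 0.05)
  est <- mr_weighted_median(make_harmonized(rep(1, 5), 0.001, ratios, 1),
                            n_boot = 10, seed = 1)
  expect_equal(est$beta, stats::median(ratios))
})

test_that("identical ratios collapse the weighted median with tiny bootstrap SE", {
  bx <- c(0.05, 0.10, 0.15, 0.2)
  est <- mr_weighted_median(make_harmonized(bx, 1e-6, 0.25 * bx, 1e-6),
                            n_boot = 200, seed = 2)
  expect_equal(est$beta, 0.25, tolerance = 1e-4)
  expect_lt(est$se, 1e-3)
})

test_that("estimators are invariant to SNP ordering and allele reorientation", {
  set.seed(13)
  k <- 8
  bx <- stats::rnorm(k, 0.1, 0.03)
  by <- stats::rnorm(k, 0.03, 0.01)
  sy <- stats::runif(k, 0.008, 0.02)
  h <- make_harmonized(bx, 0.004, by, sy)
  perm <- sample(k)
  hp <- make_harmonized(bx[perm], 0.004, by[perm], sy[perm],
                        snp_id = h$records$snp_id[perm])
  expect_equal(mr_ivw(hp)$beta, mr_ivw(h)$beta)
  expect_equal(mr_ivw(hp)$se, mr_ivw(h)$se)
  expect_equal(mr_egger(hp)$slope$beta, mr_egger(h)$slope$beta)
  # same seed, permuted rows: identical weighted-median point and SE
  expect_equal(mr_weighted_median(hp, n_boot = 100, seed = 3),
               mr_weighted_median(h, n_boot = 100, seed = 3))

  # simultaneous sign flips of (beta_exp, beta_out) leave IVW untouched
  flip <- sample(c(-1, 1), k, replace = TRUE)
  hf <- make_harmonized(bx * flip, 0.004, by * flip, sy,
                        snp_id = h$records$snp_id)
  expect_equal(mr_ivw(hf)$beta, mr_ivw(h)$beta)
  expect_equal(mr_ivw(hf)$se, mr_ivw(h)$se)
})

test_that("binary outcomes report a log-symmetric odds-ratio CI", {
  h <- make_harmonized(c(0.1, 0.12, 0.2), 0.004, c(0.04, 0.02, 0.05), 0.01,
                       binary = TRUE)
  for (est in list(mr_ivw(h), mr_egger(h)$slope,
                   mr_weighted_median(h, n_boot = 50, seed = 1))) {
    expect_equal(est$or_, exp(est$beta))
    expect_equal(sqrt(est$or_ci_low * est$or_ci_high), est$or_,
                 tolerance = 1e-12)
    expect_equal(est$ci_low, est$beta - stats::qnorm(0.975) * est$se)
    expect_equal(est$pval, 2 * stats::pnorm(-abs(est$beta / est$se)))
  }
  hc <- make_harmonized(c(0.1, 0.12, 0.2), 0.004, c(0.04, 0.02, 0.05), 0.01,
                        binary = FALSE)
  expect_true(is.na(mr_ivw(hc)$or_))
})

test_that("summary conversion reproduces reported effect triples", {
  s0 <- estimate_to_summary(0, 0.1)
  expect_equal(s0$or_, 1)
  expect_equal(s0$pval, 1)
  expect_equal(s0$ci_low * s0$ci_high, 1, tolerance = 1e-12)

  # protective odds ratio on the log-odds scale; absolute agreement at the
  # 3-decimal reporting precision
  s <- estimate_to_summary(-0.6330, 0.2877)
  expect_lt(abs(s$or_ - 0.531), 1e-3)
  expect_lt(abs(s$ci_low - 0.302), 1e-3)
  expect_lt(abs(s$ci_high - 0.933), 1e-3)
  expect_lt(abs(s$pval - 0.028), 2e-3)

  # continuous outcome: beta-scale CI, no exponentiation
  s2 <- estimate_to_summary(-0.100, 0.0411, binary_outcome = FALSE)
  expect_true(is.na(s2$or_))
  expect_lt(abs(s2$ci_low - (-0.180)), 1e-3)
  expect_lt(abs(s2$ci_high - (-0.019)), 1e-3)
  expect_lt(abs(s2$pval - 0.015), 2e-3)
})

test_that("mr_all_methods reports per-method rows with preconditions honoured", {
  h2 <- make_harmonized(c(0.1, 0.15), 0.004, c(0.03, 0.05), 0.01)
  tab <- mr_all_methods(h2, n_boot = 20, seed = 1)
  expect_identical(tab$method, c("ivw_re", "egger", "weighted_median"))
  expect_false(is.na(tab$beta[1]))
  expect_true(all(is.na(tab$beta[2:3])))
  expect_match(tab$note[2], ">= 3 SNPs")

  h5 <- make_harmonized(seq(0.05, 0.25, length.out = 5), 0.004,
                        seq(0.02, 0.08, length.out = 5), 0.01)
  tab5 <- mr_all_methods(h5, n_boot = 20, seed = 1)
  expect_false(any(is.na(tab5$beta)))
  expect_false(is.na(tab5$egger_intercept[tab5$method == "egger"]))
})
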