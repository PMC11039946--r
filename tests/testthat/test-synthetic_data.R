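test_that("simulation output is bit-identical under a fixed seed", {
  cfg <- sim_config(m = 300, theta = 0.2, seed = 11,
                    ld_blocks = list(list(size = 4, r = 0.9)))
  a <- simulate_two_sample(cfg)
  b <- simulate_two_sample(cfg)
  expect_identical(a$exposure$records, b$exposure$records)
  expect_identical(a$outcome$records, b$outcome$records)
  expect_identical(a$truth, b$truth)
  expect_identical(a$ld, b$ld)
  c <- simulate_two_sample(sim_config(m = 300, theta = 0.2, seed = 12,
                                      ld_blocks = list(list(size = 4, r = 0.9))))
  expect_false(identical(a$exposure$records$beta, c$exposure$records$beta))
})

test_that("observed exposure noise matches the stated SE model", {
  cfg <- sim_config(m = 6000, frac_palindromic = 0, frac_flipped = 0,
                    gamma_null_frac = 0.5, seed = 21)
  sim <- simulate_two_sample(cfg)
  tr <- sim$truth$snps
  ex <- sim$exposure$records
  z <- (ex$beta - tr$gamma[match(ex$snp_id, tr$snp_id)]) / ex$se
  expect_lt(abs(stats::sd(z) - 1), 0.05)
  # SE formula itself: 1/sqrt(2 n maf (1-maf))
  expect_equal(ex$se, 1 / sqrt(2 * cfg$n_exp * ex$eaf * (1 - ex$eaf)))
})

test_that("null causal effect yields a near-zero strength-weighted ratio", {
  sim <- simulate_two_sample(sim_config(m = 100, theta = 0, pi_invalid = 0,
                                        gamma_null_frac = 0, frac_flipped = 0,
                                        seed = 1))
  ex <- sim$exposure$records
  ou <- sim$outcome$records
  w <- (ex$beta / ou$se)^2
  pooled <- sum(w * (ou$beta / ex$beta)) / sum(w)
  se_pooled <- sqrt(1 / sum((ex$beta / ou$se)^2))
  expect_lt(abs(pooled), 3 * se_pooled)
})

test_that("the truth record never leaks into the emitted tables", {
  sim <- simulate_two_sample(sim_config(m = 50, seed = 3))
  for (tab in list(sim$exposure$records, sim$outcome$records)) {
    expect_false(any(c("gamma", "alpha", "valid", "block") %in% names(tab)))
  }
})

test_that("flipped outcome rows are exact allele swaps and harmonization undoes them", {
  base <- list(m = 200, theta = 0.25, gamma_null_frac = 0.7,
               frac_palindromic = 0, seed = 31)
  flip <- simulate_two_sample(do.call(sim_config, c(base, frac_flipped = 1)))
  noflip <- simulate_two_sample(do.call(sim_config, c(base, frac_flipped = 0)))
  expect_identical(flip$outcome$records$effect_allele,
                   noflip$outcome$records$other_allele)
  expect_identical(flip$outcome$records$other_allele,
                   noflip$outcome$records$effect_allele)
  expect_equal(flip$outcome$records$beta, -noflip$outcome$records$beta)
  expect_equal(flip$outcome$records$eaf, 1 - noflip$outcome$records$eaf)

  inst <- select_instruments(flip$exposure)
  h_flip <- harmonize_pair(inst, flip$outcome)
  h_noflip <- harmonize_pair(select_instruments(noflip$exposure),
                             noflip$outcome)
  expect_true(all(h_flip$records$action == "kept_flipped"))
  expect_equal(h_flip$records$beta_out, h_noflip$records$beta_out)
})

test_that("LD blocks give a structured matrix and clumping keeps one SNP per block", {
  cfg <- sim_config(m = 40, gamma_null_frac = 0, frac_palindromic = 0,
                    ld_blocks = list(list(size = 5, r = 0.9),
                                     list(size = 3, r = 0.5)),
                    seed = 41)
  sim <- simulate_two_sample(cfg)
  expect_identical(dim(sim$ld), c(8L, 8L))
  expect_identical(sim$ld, t(sim$ld))
  expect_equal(unname(diag(sim$ld)), rep(1, 8))
  expect_equal(unname(sim$ld[1, 2]), 0.9)
  expect_equal(unname(sim$ld[6, 7]), 0.5)
  # block members scale the lead gamma by r
  tr <- sim$truth$snps
  expect_equal(tr$gamma[2:5], rep(0.9 * tr$gamma[1], 4))

  inst <- select_instruments(sim$exposure, ld = sim$ld)
  kept_per_block <- table(tr$block[match(inst$records$snp_id, tr$snp_id)])
  expect_true(all(kept_per_block[names(kept_per_block) != "0"] == 1))
})

test_that("palindromic fraction controls complementary allele pairs", {
  sim <- simulate_two_sample(sim_config(m = 400, frac_palindromic = 1,
                                        seed = 51))
  expect_true(all(is_palindromic(sim$exposure$records$effect_allele,
                                 sim$exposure$records$other_allele)))
  sim0 <- simulate_two_sample(sim_config(m = 400, frac_palindromic = 0,
                                         seed = 51))
  expect_false(any(is_palindromic(sim0$exposure$records$effect_allele,
                                  sim0$exposure$records$other_allele)))
})

test_that("degenerate maf ranges are rejected; zero-width allowed", {
  expect_error(sim_config(maf_range = c(0, 0.5)), class = "mr_config_error")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), class = "mr_config_error")
  sim <- simulate_two_sample(sim_config(m = 10, maf_range = c(0.3, 0.3),
                                        seed = 1))
  expect_equal(sim$exposure$records$eaf, rep(0.3, 10))
})

test_that("replicate driver reports rejection rate and skips barren replicates", {
  rep <- simulate_replicates(
    sim_config(m = 300, theta = 0, gamma_null_frac = 0.8, seed = 61),
    n_reps = 5, methods = c("ivw_re", "weighted_median"), n_boot = 100)
  expect_identical(sort(unique(rep$estimates$method)),
                   c("ivw_re", "weighted_median"))
  expect_true(all(rep$summary$rejection_rate >= 0 &
                    rep$summary$rejection_rate <= 1))
  expect_identical(rep$estimates$seed[rep$estimates$method == "ivw_re"],
                   61L + 0:4)

  # all-null gammas: no instrument ever reaches the fallback threshold
  barren <- simulate_replicates(
    sim_config(m = 50, gamma_null_frac = 1, seed = 71), n_reps = 3)
  expect_equal(barren$n_failed, 3)
})

test_that("simulation files round-trip through the writers", {
  dir <- withr::local_tempdir()
  sim <- simulate_two_sample(sim_config(m = 30, seed = 81,
                                        ld_blocks = list(list(size = 3, r = 0.7))))
  files <- write_simulation(sim, file.path(dir, "sim_"))
  ex <- read_sumstats(file.path(dir, "sim_exposure.tsv"), "sim_exposure")
  expect_equal(ex$records, sim$exposure$records)
  ld <- read_ld_matrix(file.path(dir, "sim_ld.tsv"))
  expect_equal(ld, sim$ld)
  truth <- jsonlite::read_json(file.path(dir, "sim_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$theta, sim$truth$theta)
})
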