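---
title: "Two-sample Mendelian randomization with mrpipe: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure (here: circulating
sex hormones, their receptors, and sex hormone-binding globulin) on an
outcome (inflammatory bowel disease and its subtypes), exploiting the
random assortment of alleles at conception. In the *two-sample* design the
SNP-exposure and SNP-outcome associations come from separate GWAS, so the
raw material is two summary-statistics tables: per SNP, an effect allele,
an effect estimate, its standard error, a p-value, and (optionally)
frequency and sample size.

mrpipe implements the full analysis chain on such tables: instrument
selection, allele harmonization, three causal estimators, a sensitivity
battery, a two-criterion robustness verdict, and batch orchestration over
bidirectional, sex-stratified exposure-outcome grids. Because the original
hormone and IBD GWAS are not redistributable here, the package ships a
generator of paired summary statistics under a known structural model, so
that every stage — and every statistical claim the test suite makes — can
be checked against known truth.

## Instrument selection

A SNP becomes an instrument when it passes three filters, in this order:

1. **Significance.** Genome-wide significance `p < 5e-8`. If fewer than
   two SNPs survive the subsequent clumping step, selection restarts from
   the full table at the relaxed threshold `p < 5e-6`. The threshold
   actually used is recorded on the instrument set and in the audit trail.
   The fallback is evaluated per exposure independently.
2. **Independence.** Greedy LD clumping: repeatedly keep the unprocessed
   SNP with the smallest p-value and remove every unprocessed SNP on the
   same chromosome within 10,000 kb whose squared correlation with it is
   at least 0.001. Ties on p-value break by genomic coordinate, then by
   identifier, which makes the result independent of input row order and
   idempotent. LD comes from a user-supplied correlation matrix (the
   generator exports one); there is no reference-panel clumping, and SNPs
   absent from the matrix are treated as unlinked with a logged note.
3. **Strength.** The per-SNP F statistic `F = beta^2 / se^2` must exceed
   10 *strictly*. The F filter runs after clumping; the audit trail
   records the order so either arrangement can be inspected. (The two
   filters commute in their set effect whenever the clump survivors are
   the same, which the audit makes checkable.)

Every input SNP ends in exactly one audit state: `kept`, `dropped_pval`,
`dropped_ld`, or `dropped_weak`.

## Harmonization

Outcome records are aligned to the exposure effect allele. Per instrument
SNP: missing from the outcome → dropped (no proxy lookup, by design);
palindromic allele pair (A/T or C/G) on either side → dropped
unconditionally, with no frequency-based strand inference — the
ambiguity-free subset is preferred over frequency heuristics; identical
allele pair → kept as-is; swapped pair → kept with the outcome beta
negated and the frequency complemented; anything else → mismatch, dropped.
The kept set plus the per-SNP drop reasons partition the instrument set,
and harmonizing a dataset whose outcome table was emitted entirely
allele-swapped reproduces, bit for bit, the harmonized betas of the
unswapped run with the same seed (the generator draws all randomness
unconditionally precisely so this involution is exactly testable).

## Estimators

All inference is z-based: two-sided normal p-values and
`beta ± 1.96 · se` confidence intervals; binary outcomes exponentiate to
odds ratios (the 95% CI of the OR is log-symmetric, so the printed OR is
the geometric mean of its bounds — a redundancy the acceptance suite
exploits).

**IVW (primary).** Weighted least squares of outcome betas on exposure
betas through the origin with weights `1/se_out^2`. The random-effects
flavor is *multiplicative*: the fixed-effect SE is scaled by
`max(1, sqrt(Q/(k-1)))`, where Q is Cochran's Q over the Wald ratios. The
floor at 1 means heterogeneity can only widen intervals; with a single SNP
the method degrades to the Wald ratio `beta_out/beta_exp` (first-order SE
`se_out/|beta_exp|`) and notes it.

**MR-Egger.** Each SNP is oriented so its exposure beta is nonnegative
(both betas flipped together — required for the intercept to be
interpretable), then a weighted regression *with* intercept is fitted.
The slope is a pleiotropy-adjusted causal estimate, valid under the
InSIDE assumption; the intercept estimates the mean directional
pleiotropic effect, and its z test is the pleiotropy check. Both SEs carry
the same multiplicative dispersion (weighted residual mean square on k−2
df, floored at 1).

**Weighted median.** Wald ratios with first-order inverse-variance
weights `(se_out/beta_exp)^-2`; the estimate interpolates the weighted CDF
(evaluated at the midpoints `cumsum(w) − w/2`) at 0.5, so with equal
weights and odd k it is the plain sample median. It is consistent while
at least half the weight comes from valid instruments. Its SE is a
parametric bootstrap (default 1000 replicates, seed required): exposure
and outcome betas resampled from normals centred on their estimates with
their reported SEs, weights recomputed per replicate, SD of the
replicated medians reported. Second-order ratio weights are deliberately
not the default anywhere; first-order weights are used consistently.

A note on calibration: the parametric bootstrap SD is a slightly
conservative SE for a non-smooth statistic like the median. Under the
generator's null conditions it exceeds the estimator's empirical sampling
SD by roughly 12%, so the weighted median's type-I error sits near 0.027
rather than 0.05. The replicate suites report this honestly; IVW and
MR-Egger hold their nominal size. Users should read weighted-median
p-values as conservative.

## Sensitivity battery

* **Cochran's Q** over Wald ratios with weights `(beta_exp/se_out)^2`,
  referred to chi-square on k−1 df. By construction Q/(k−1) is exactly the
  dispersion the random-effects IVW uses — one definition, asserted in
  the tests. Heterogeneity never invalidates a result by itself (the
  random-effects SE absorbs it); it only annotates the report.
* **MR-Egger intercept test**: two-sided z test of the intercept.
* **MR-PRESSO.** The observed residual sum of squares uses leave-one-out
  IVW slopes: `RSS = sum_j w_j (beta_out_j − theta_(−j) beta_exp_j)^2`.
  Its null distribution is simulated (default 1000 datasets): outcome
  betas drawn around `theta_(−j) · beta_exp_j` with SD `se_out_j`,
  exposure betas jittered with `se_exp_j`. Global p uses the
  `(1 + exceedances)/(n_sim + 1)` convention (never exactly zero); per-SNP
  outlier p-values compare each observed weighted residual with its
  simulated counterparts and are Bonferroni-multiplied by k, flagging
  SNPs below 0.05. When outliers are found, the corrected estimate is the
  random-effects IVW without them, and the distortion coefficient
  `100 · (theta_corrected − theta_all)/|theta_all|` is referred to the
  two-sided distribution of coefficients from removing equally many SNPs
  uniformly at random. Simulated noise attaches to SNPs in identifier
  order, so every Monte-Carlo p-value is invariant to input row order
  under a fixed seed.

Availability rules: Q needs ≥ 2 instruments, the intercept test ≥ 3,
MR-PRESSO ≥ 4. Below these the report marks the component unavailable
with the reason rather than guessing.

## Robustness verdict and batching

A finding is *relatively robust* when (a) IVW is significant at p < 0.05
and (b) the causal estimates of all available methods share one
direction. When a method is unavailable (too few instruments) it is
excluded from the comparison and the reduced comparison is listed on the
verdict, so the caller can see that fewer than three methods agreed. No
multiple-testing correction is applied across the exposure-outcome grid —
findings are reported at unadjusted p < 0.05, and the grid driver treats
each (exposure, outcome, stratum, direction) cell independently.
Sex-stratified analyses are plain manifest entries: stratification lives
entirely in the input GWAS tables. Forward and reverse analyses select
instruments independently; nothing is shared between directions. A pair
whose selection or harmonization fails contributes a "not estimable" row
rather than aborting the study, and a whole-study run under a fixed seed
is bit-reproducible.

## The generator

`simulate_two_sample()` draws, per SNP j: a minor-allele frequency
`MAF_j ~ U(0.05, 0.5)`; a true instrument effect `gamma_j` that is 0 with
probability 0.95 and `N(0.08, 0.03^2)` otherwise; standard errors
`1/sqrt(2 n MAF (1−MAF))` for a standardized trait on each side (binary
outcomes reuse the formula as a log-odds-scale approximation); observed
betas `N(gamma_j, se_exp^2)` and `N(theta·gamma_j + alpha_j, se_out^2)`
with independent noise (the two-sample assumption); horizontal pleiotropy
`alpha_j ~ N(mu_alpha, sigma_alpha^2)` on an invalid fraction of SNPs.
Optional LD blocks impose a constant pairwise correlation on exposure
sampling errors and scale non-lead gammas by the block correlation; the
block structure is exported as the LD matrix the clumper consumes.
Fractions of SNPs receive palindromic allele pairs (default 0.2) and
swapped-allele outcome rows (default 0.3) to exercise harmonization.
Default sample sizes — 200,000 for the exposure, 35,000 for the outcome —
mirror a modern biobank-scale hormone GWAS against a disease GWAS of
roughly the combined IBD case/control size, and the default panel of
2,000 candidate SNPs with 5% true instruments yields on the order of
60–90 instruments after selection and harmonization, comparable to the
better-instrumented hormone traits.

What the generator does *not* emulate: individual-level genotypes,
case-control ascertainment, sample overlap between the two GWAS, allele
frequency differences between studies, population stratification, and
winner's-curse-inducing discovery/replication structure beyond plain
threshold selection. Passing tests therefore validate the pipeline's
statistical behaviour under the stated model, not the epidemiological
correctness of any particular real-data finding.

## Problem sizes and numerical choices

The replicate suites run 500 null replicates for size (the exact binomial
95% band around 0.05 at 500 replicates is [0.032, 0.071]) and 200
replicates for recovery means; MR-PRESSO behaviour is checked over 100
planted-outlier runs and 200 null runs at 1000 simulated datasets each.
These sizes put Monte-Carlo error well below the effects being asserted
while keeping the default suite fast.

Two recovery checks deserve a note on their comparison scales. The IVW
mean at `theta = 0.3` and the Egger intercept mean at `mu_alpha = 0.1`
are compared within two standard errors *of the mean* — the strict scale.
For the weighted median under one-sided contamination (30% invalid
instruments, directional pleiotropy), the estimator converges to the
`0.5/(1−π)` quantile of the valid-ratio distribution, an irreducible
finite-sample shift of order `z_{0.71} · sd(ratio)` that, like the SE of
the mean, scales with the ratio noise — so no instrument count or noise
level can bring the mean within two SEs of the mean of truth. That
property is therefore assessed at the scale of the estimator's own
sampling SD, together with the sharper and more diagnostic comparison:
the weighted median must land closer to truth than IVW while IVW is
detectably biased. The contamination scenario uses ~25 instruments
(600 candidate SNPs), an instrument count typical of the hormone traits,
where the quantile shift is small relative to the sampling SD.

Other numerical choices: p-values in the generator are clamped to the
smallest positive double so genome-wide hits survive the `0 < p ≤ 1`
validation invariant; Monte-Carlo p-values use `+1` smoothing; the
clumping tie-break (p-value, coordinate, identifier) pins down the
survivor set exactly; degenerate designs (all exposure betas zero,
singular Egger design) raise classed errors rather than returning
numbers; and all derived seeds are small integer offsets of the base
seed.

## Worked example

```{r example}
sim <- simulate_two_sample(sim_config(m = 1000, theta = 0.3, seed = 7))
res <- run_pair(sim$exposure, sim$outcome, ld = sim$ld,
                config = mr_config(seed = 7))
res$estimates[, c("method", "n_snp", "beta", "se", "pval")]
res$verdict
res$sensitivity
```

The IVW row is the primary estimate (log-odds per exposure SD, with
odds-ratio columns alongside); MR-Egger and the weighted median are the
pleiotropy-robust companions entering the direction check; the
sensitivity report carries Q, the Egger intercept and the MR-PRESSO
results for the same instruments.

## Known limitations

* No reference-panel LD: clumping requires a supplied correlation matrix
  and otherwise treats SNPs as unlinked.
* No proxy-SNP lookup for instruments missing from the outcome, and no
  Steiger directionality filtering or multivariable extension.
* Palindromic SNPs are always discarded; with many palindromic
  instruments this costs power by design.
* Continuous exposures are assumed standardized; no unit rescaling is
  attempted.
* Weighted-median inference is conservative (bootstrap SE, see above).
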