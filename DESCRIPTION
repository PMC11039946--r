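Package: mrpipe
Title: Two-Sample Mendelian Randomization Pipelines with Synthetic GWAS
    Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-sample Mendelian randomization from
    GWAS summary statistics: instrument selection (genome-wide significance
    with a relaxed fallback threshold, greedy LD clumping, F-statistic
    filtering), allele harmonization with unconditional exclusion of
    palindromic variants, three causal estimators (multiplicative
    random-effects inverse-variance weighted, MR-Egger regression, weighted
    median with parametric-bootstrap standard errors), a sensitivity battery
    (Cochran's Q, MR-Egger intercept test, MR-PRESSO global, outlier and
    distortion tests), a two-criterion robustness verdict, and batch
    orchestration of bidirectional, sex-stratified exposure-outcome grids.
    Includes a generator of paired exposure/outcome summary statistics under
    a known structural model (instrument effects, horizontal pleiotropy, LD
    blocks, palindromic and allele-flipped variants) so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
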