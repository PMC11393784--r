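Package: twostepmr
Title: Bidirectional Two-Sample Mendelian Randomization with Two-Step Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from GWAS summary
    statistics: instrument selection (p-value thresholding, greedy LD clumping,
    F-statistic filtering), allele harmonization with palindromic-variant
    resolution, a five-estimator causal suite (inverse-variance weighted with
    fixed/random/auto effects, MR-Egger, weighted median, simple and weighted
    mode), heterogeneity and pleiotropy diagnostics (Cochran's Q, Egger
    intercept, leave-one-out, MR-PRESSO global/outlier/distortion tests), and
    two-step mediation analysis combining exposure-outcome, exposure-mediator
    and mediator-outcome effects into indirect effects and mediated proportions
    with delta-method confidence intervals. Includes a synthetic
    summary-statistics generator for an exposure-mediator-outcome causal chain
    with configurable pleiotropy, used throughout the test suite as ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
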