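Package: ivmr
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Instrument selection, allele harmonization, and causal-effect
    estimation for two-sample Mendelian randomization from GWAS summary
    statistics. Implements the Wald ratio, inverse-variance-weighted (fixed
    and multiplicative random effects), weighted-median (parametric
    bootstrap standard errors), and MR-Egger estimators; heterogeneity
    (Cochran's Q), directional-pleiotropy (Egger intercept), outlier
    (MR-PRESSO) and leave-one-out diagnostics; binary-outcome power
    calculation with inversion to the minimum detectable odds ratio; and a
    seeded generator of two-sample summary statistics with known ground
    truth for method evaluation. Ships the serum 25-hydroxyvitamin D,
    calcium and parathyroid hormone instruments for coronary artery disease
    in diabetes as worked example data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
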