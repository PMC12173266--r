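Package: medmr
Title: Two-Sample Mendelian Randomization with Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-sample Mendelian randomization (MR)
    mediation analysis of GWAS summary statistics: instrument selection
    (p-value screen, greedy LD clumping, F-statistic filter), allele
    harmonization with palindromic-variant handling, causal-effect
    estimation (inverse-variance weighted, MR-Egger, weighted median),
    pleiotropy and heterogeneity diagnostics (Egger intercept, Cochran Q,
    leave-one-out, MR-PRESSO), and two-step mediation with the product of
    coefficients and delta-method intervals. Includes a summary-statistics
    simulator that generates three non-overlapping GWAS cohorts under an
    explicit exposure-mediator-outcome structural model, so every stage is
    verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp
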