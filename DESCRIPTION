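Package: mrscreen
Title: Two-Sample Mendelian Randomization Screening of GWAS Summary
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Univariable bi-directional and multivariable two-sample
    Mendelian randomization for screening many exposures (such as gut
    microbial taxa) against a GWAS outcome from summary statistics alone.
    Implements instrument selection (p-value screen, greedy LD clumping,
    F-statistic filter), allele harmonization with palindrome and proxy
    handling, the inverse-variance-weighted, maximum-likelihood, MR-Egger,
    weighted-median and weighted-mode estimators, the MR-PRESSO global,
    outlier and distortion tests, constrained maximum likelihood with
    BIC model averaging (cML-MA-BIC), Cochran's Q, leave-one-out and
    confounder-annotation diagnostics, multivariable MR, and a synthetic
    summary-statistic generator with known truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
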