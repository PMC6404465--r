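Package: mrtwosample
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimators and diagnostics for two-sample Mendelian
    randomization with GWAS summary statistics: inverse-variance weighted
    and weighted median estimators, MR-Egger regression with the I2(GX)
    instrument-strength statistic and SIMEX dilution correction, the
    MR-PRESSO global/outlier/distortion tests, heterogeneity-penalized
    model averaging, leave-one-out and named-SNP exclusion reanalysis, a
    Brion-style binary-outcome power calculation, allele harmonization
    with configurable palindromic-SNP policies, and a fully seeded
    synthetic summary-statistics generator so the complete stack can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
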