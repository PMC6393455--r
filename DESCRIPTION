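Package: vitdmr
Title: Two-Sample Mendelian Randomization of Vitamin D Status and Fatigue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for two-sample Mendelian
    randomization (MR) of circulating 25-hydroxyvitamin D (25OHD) on
    self-reported fatigue, and for two-sample MR with GWAS summary
    statistics more generally.  Provides summary-statistic input/output
    and validation, effect-allele harmonization to the
    exposure-decreasing allele, inverse-variance-weighted, weighted
    median and MR-Egger estimators with heterogeneity and pleiotropy
    diagnostics, leave-one-out and single-SNP sensitivity analyses,
    bidirectional MR, polygenic-score confounder checks, analytic MR
    power for binary outcomes, DerSimonian-Laird random-effects
    meta-analysis of standardized mean differences, and a synthetic
    two-sample GWAS generator with known ground truth so that every
    stage of the pipeline is testable without access to external
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    metafor,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
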