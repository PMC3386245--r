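Package: decohort
Title: Case-Control Transcriptomic Cohorts: Differential Expression,
    TFBS Enrichment, eSNP Interaction, Mediation and Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidy toolkit for post-mortem brain case/control expression
    studies and their downstream genetics. Implements probe-level quality
    filtering and quantile normalization for one-color microarray exports,
    covariate-adjusted per-probe differential expression with
    Benjamini-Hochberg FDR control, transcription-factor binding-site
    gene-set enrichment with fold-enrichment and direction-of-change
    chi-square tests, a 2-df genotype plus genotype-by-status eSNP model
    with an eigenvalue-based effective-number-of-tests correction,
    linear/logistic mediation decomposition with standardized betas and a
    Sobel Z test, and two summary-statistic meta-analysis engines
    (sample-size weighted Z and inverse-variance with genomic control).
    A seeded synthetic-cohort generator reproduces the statistical
    structure of such studies so every stage runs end-to-end without
    access to the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
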