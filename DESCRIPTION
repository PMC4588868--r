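Package: methmediate
Title: EWAS and Mediation Analysis of Prenatal Smoking Effects on Birthweight via Cord Blood DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for epigenome-wide association studies (EWAS) of
    Illumina 450K-style methylation beta matrices, and for Baron-Kenny mediation
    of an exposure effect on a continuous outcome through CpG methylation.
    Includes detection p-value based quality filtering of samples and probes,
    single imputation of covariates, reference-based (Houseman-style) cell-type
    deconvolution, covariate-adjusted per-CpG linear models with
    Benjamini-Hochberg and Bonferroni control, dose-response testing, Sobel
    inference with mediation percentages, fixed-effects inverse-variance
    meta-analysis across cohorts (with standard-error recovery from printed
    p-values), and a synthetic multi-cohort data generator that emulates
    cell-type composition confounding and a partially mediated exposure effect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    pracma,
    withr,
    digest
Suggests:
    testthat (>= 3.0.0),
    metafor,
    knitr,
    rmarkdown
Config/testthat/edition: 3
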