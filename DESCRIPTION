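Package: mrpipe
Title: Two-Sample and Individual-Level Mendelian Randomization Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tidyverse-native toolkit for Mendelian randomization (MR)
    analyses of a quantitative exposure on a binary outcome, modelled on
    the design of published anthropometric-trait MR studies. Implements
    GWAS summary-statistic input/output and allele harmonization
    (including palindromic strand inference), greedy LD clumping,
    instrument-strength diagnostics (per-variant R-squared and F),
    sample-overlap bias approximation, the inverse-variance-weighted,
    MR-Egger, weighted-median and MR-PRESSO estimators, Cochran's Q,
    multivariable and bidirectional MR, effect rescaling between
    per-standard-deviation and natural units, weighted standardized
    genetic risk scores, two-stage instrumental-variable regression for
    binary outcomes with sandwich standard errors, cohort descriptive
    tables, phecode-based phenome-wide association scans, and a fully
    deterministic synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lmtest,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
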