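Package: cnasd
Title: Size-Dependent Copy-Number Alteration Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering prognostic, size-dependent somatic
    copy-number alterations (CNAs) from segmented copy-number profiles and
    time-to-event outcomes. Converts SEG-format segment tables into per-arm
    percent-altered fractions on a 30 kb grid, sweeps binary CNA calls across
    1-99% arm-size thresholds scored by 5-year time-dependent ROC AUC under
    univariate Cox models, flags size-dependent CNAs by AUC, AUC-variability
    and prevalence criteria with a permutation/bootstrap false discovery rate
    for the variability cutoff, scans 200 kb sliding windows for focal
    prognostic regions, models CNA co-occurrence with cross-validated
    regularized Cox regression and burden-adjusted models, stratifies CNA
    burden by log-rank recursive partitioning, and combines selected CNAs
    into a boosted linear Cox risk score with percentile risk groups. A
    seeded synthetic-cohort simulator with planted arm-level, focal,
    co-occurrence and burden effects supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
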