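Package: longvol
Title: Longitudinal and Paired-Sample Analysis of Microbiome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal and paired-sample analysis of microbiome
    metrics and feature tables: within-subject temporal transforms (first
    differences and first distances, baseline and static-reference
    comparisons), control-chart volatility statistics and plots, paired
    difference and distance tests, linear mixed-effects models with random
    intercepts and slopes, and a supervised-regression feature-volatility
    pipeline that identifies features whose abundance predicts time. Includes
    a synthetic longitudinal cohort simulator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    ranger,
    glmnet,
    xgboost,
    jsonlite,
    ggplot2,
    rlang,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
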