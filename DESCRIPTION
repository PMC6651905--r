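Package: markstrat
Title: Bimodal Marker Stratification, Survival and Co-Expression Analysis for
    Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Dichotomizes tumor cohorts by a bimodally expressed marker gene
    using density-valley thresholds pooled across cohorts or two-component
    Gaussian-mixture ratio crossings, compares disease-free survival between
    the resulting strata with Kaplan-Meier curves and the log-rank test,
    screens individual genes for prognostic impact, characterizes the
    marker's co-expression neighborhood via Spearman correlation with
    Benjamini-Hochberg FDR control and cross-cohort maximum-rank
    aggregation, and tests associations with clinicopathological covariates.
    Includes a multi-cohort synthetic-data generator emulating bimodal
    activity scores, rank-correlated gene modules and stratum-dependent
    right-censored survival, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
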