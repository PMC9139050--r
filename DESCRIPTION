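Package: neutroclust
Title: Neutrophil-Count Phenotype Clustering for Bronchiectasis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven discovery of a blood-neutrophil cut-off that splits a
    non-cystic-fibrosis bronchiectasis cohort into two clinical phenotypes, and
    the downstream characterization of the resulting clusters. Provides
    table-driven FACED, E-FACED and BSI severity-score calculators with
    mild/moderate/severe binning, a Mann-Whitney U threshold sweep with
    significance and balance based selection strategies, two-group comparison
    tables with significance stars and subgroup-exclusion re-analyses, pairwise
    Pearson correlation matrices, confounder-adjusted logistic regression with
    Wald intervals and separation diagnostics, and a synthetic patient-registry
    generator with a planted threshold effect so the whole pipeline is testable
    without access to registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    tidyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
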