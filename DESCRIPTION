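Package: adcomorbid
Title: Stratified Comorbidity Analysis of Alzheimer's Dementia EMR Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deep-phenotyping pipeline for race/ethnicity-stratified
    comorbidity analysis of Alzheimer's dementia in OMOP-style electronic
    medical record data. Provides a synthetic EMR cohort generator with
    configurable stratum- and site-specific comorbidity effects, ICD-to-phecode
    phenotype mapping, two-round propensity-score nearest-neighbor matching
    with balance diagnostics, per-stratum case-control differential analysis
    (Fisher's exact or chi-squared with Bonferroni correction and odds ratios),
    UMAP phenotype-profile embedding comparisons via rank tests with Dunn's
    post hoc procedure, prevalence-thresholded disease co-occurrence networks
    with ten node-topology metrics, and two-site replication and concordance
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    uwot
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
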