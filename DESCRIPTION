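Package: mmstrat
Title: Ancestry-Stratified Somatic Analysis of Multiple Myeloma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing somatic alteration profiles between
    genetic-ancestry strata of a tumor cohort.  Provides exome-scale
    supervised admixture estimation from ancestry-informative markers,
    genotype principal-component analysis, a self-report concordance
    filter, multi-caller somatic consensus under a 2-of-3 rule,
    cross-cohort differential mutation-frequency testing with exact
    statistics and Benjamini-Hochberg correction, copy-number-aware
    TP53 locus-state classification (wildtype / mono-allelic /
    bi-allelic), hyperdiploidy karyotyping from segment tables,
    expression risk-signature scoring, Kaplan-Meier survival
    stratification, and a seeded synthetic-cohort generator producing
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
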