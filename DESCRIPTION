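Package: plasmatrace
Title: Tumor-Informed ctDNA Detection and Longitudinal Monitoring from
    Plasma Variant Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tumor-informed longitudinal monitoring of circulating
    tumor DNA (ctDNA) from targeted-panel variant-call tables. Provides
    post-call somatic filtering of baseline tumor-tissue variants, a
    database-plus-allele-frequency logistic classifier separating germline
    from somatic calls without a matched normal, a Monte Carlo empirical
    p-value test for ctDNA presence against each plasma sample's background
    allele alterations, total-ctDNA quantification in mutated genome
    equivalents, molecular-progression and lead-time calling from allele
    frequency trajectories, and progression-free survival analysis
    (Kaplan-Meier, log-rank, univariate Cox) stratified by ctDNA status.
    Includes a ground-truth-labelled synthetic cohort generator so the whole
    pipeline is testable end to end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
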