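Package: ancestryburden
Title: Ancestry-Stratified Pathogenic Variant Burden Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for counting known pathogenic/likely-pathogenic (P/LP) and
    predicted loss-of-function (pLoF) variants in an actionable gene panel
    across genetically predicted ancestry groups. Implements knowledge-base
    filtering (curated P/LP databases, ClinVar star/date rules, population
    frequency tables), genotype-quality and zygosity-aware variant selection,
    contingency statistics with sparse-cell aggregation, a pooled
    two-proportion z-test with Bonferroni control, external allele-frequency
    comparisons with reference-database subsets, phenotype-cohort enrichment
    tests, and a fully synthetic cohort simulator so the whole pipeline is
    testable without controlled-access data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
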