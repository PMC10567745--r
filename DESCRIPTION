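Package: spliceburden
Title: Splice-Disrupting Variant Prioritisation, Burden Testing and
    ACMG/AMP Classification in Inherited Heart Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for putative splice-disrupting variants in
    definitively disease-associated inherited heart disease genes. Parses HGVS
    coding notation to classify variants into splice-region anatomy (donor,
    acceptor, exon edge, deep intronic, exonic), applies rarity and in silico
    splice-prediction thresholds (MaxEntScan, dbscSNV ADA/RF, SpliceAI) to flag
    candidate variants, performs coverage-adjusted per-gene case versus
    population burden testing with one-sided Fisher's exact tests, Bonferroni
    correction and arcsine two-proportion power, and assigns ACMG/AMP evidence
    codes at customised strengths with a point-based combiner and an
    RNA-evidence reclassification workflow. A seeded synthetic cohort generator
    emulates the case cohort, tool-score concordance and gnomAD-style control
    denominators so that every stage runs without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
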