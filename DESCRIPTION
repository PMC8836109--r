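Package: VariantFunnel
Title: Family-Based Germline Variant Prioritization Funnel
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tiered prioritization of rare germline variants in cancer-affected
    families. Annotated whole-exome variant tables are passed through an
    ordered funnel of per-variant filters: call quality and coverage,
    population and local allele frequency, pedigree-role segregation
    (obligate carriers defined by phenotype), coding and non-synonymous
    classification, PHRED-scaled CADD, a 2-of-3 conservation panel
    (GERP++, PhastCons, PhyloP), a gene-intolerance panel (three
    frequency-based intolerance scores, missense Z, pLI), and a 12-member
    dbNSFP-style deleteriousness predictor panel with a configurable
    favorable-fraction rule. Includes a carrier tally and exact association
    test for validation-cohort genotyping, an alignment-column conservation
    audit, and a seeded Mendelian gene-dropping simulator of annotated
    family variant datasets for end-to-end testing and planted-variant
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: VariantAnnotation, GeneticVariability, Genetics, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
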