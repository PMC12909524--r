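Package: kasprint
Title: KASP Marker Development, Endpoint Genotype Calling and SNP
    Fingerprinting for Germplasm Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building kompetitive allele-specific PCR (KASP)
    genotyping panels from resequencing-derived SNPs and using them to
    fingerprint germplasm collections. Covers the full workflow: a
    four-stage SNP filter cascade (minor allele frequency, missing rate,
    polymorphism information content, flanking-variant exclusion),
    flanking-sequence extraction and tailed-primer assay assembly,
    genotype calling from endpoint FAM/HEX fluorescence with no-template
    control gating and assay triage, per-marker diversity statistics,
    population structure (allele-sharing distance, neighbor-joining trees
    with bootstrap, genotype PCA, EM admixture fitting, Evanno delta-K),
    and DNA fingerprint databases with greedy minimal marker-set
    selection and query identification. A seeded synthetic-data module
    simulates admixed populations under the Balding-Nichols model and
    endpoint fluorescence plates so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    grDevices,
    graphics,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
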