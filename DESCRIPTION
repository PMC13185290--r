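Package: alleleflow
Title: Allele-Specific Expression from Barcoded Single-Cell and Long-Read Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Allele-resolved UMI counting from variant-annotated, barcoded
    alignments together with phased genotypes, at gene, SNP, peak, and isoform
    resolution for both short and long reads. Includes cohort assembly with
    haplotype orientation at a query SNP, beta-binomial allelic-imbalance tests
    (pseudobulk, mixed-model, permutation, and differential variants),
    quasi-binomial alternatives, per-cell quality-control metrics,
    hybrid-selection target-region design, and seed-deterministic synthetic
    data generators so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
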