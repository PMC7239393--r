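Package: stipper
Title: Localization and Dosage Analysis of a Sex-Linked Nested Tandem Copy
    Number Variant
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for mapping and characterizing a nested tandem
    copy number variant (CNV) at a sex-linked (Z-chromosome) locus from
    short-read cohort data. Provides a case/control allele-frequency
    differentiation scan based on a two-binomial likelihood-ratio test,
    read-depth normalization and integer copy-number estimation with
    hemizygosity-aware baselines, soft-clip pileup breakpoint detection,
    tandem-structure inference with junction-type enumeration and
    gene-effect prediction (amplification, truncation, fusion), a
    paralog-aware low-allele-fraction variant scan, delta-delta-Ct
    copy-number and relative-expression quantification, and the group
    statistics used to associate copy number with phenotype. A synthetic
    cohort generator with known truth (ZW/ZZ sex ploidy, Poisson depth
    noise, copy-private variants, noisy Ct assays) makes every stage
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
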