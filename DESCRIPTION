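Package: specpeak
Title: Cell-Type Specificity of Transcription-Factor ChIP-Seq Peaks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of how transcription-factor ChIP-seq peaks differ
    between cell types. Provides interval primitives for peak overlap,
    relative overlap and cross-factor peak clustering; genomic annotation
    (promoters with first introns, Pol III promoters, CpG classification,
    TSS distance); per-region quantification of chromatin accessibility,
    histone-mark and conservation tracks; position-weight-matrix log-odds
    motif scoring with allele-substitution rescoring for genotype
    differences; height-binned trend statistics; and linear support vector
    machine classifiers (full feature set, peak height only, and
    height/conservation/motif) that predict whether a peak found in one
    cell type is also found in another, evaluated by stratified
    cross-validation with feature-group elimination and a cross-cell-type
    protocol. A seeded synthetic-data generator emulates paired cell-type
    peak sets with known ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    IRanges,
    S4Vectors,
    Biostrings,
    vcfR,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
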