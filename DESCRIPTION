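Package: teregulome
Title: Transposable Element Contributions to Transcription Factor
    Binding and Promoter Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for quantifying the contribution of
    transposable elements (TEs) to transcriptional regulation in cancer
    genomics data. Implements permutation-based (circular genome
    rotation) enrichment testing of TE subfamilies in ChIP-seq peak
    sets with binomial tests and Bonferroni correction; epigenetic
    metaprofiles (binned RPKM with control subtraction and Epanechnikov
    smoothing) around TF-bound versus unbound TE copies, plus
    consensus-coordinate truncation profiles; hierarchical discovery of
    TE-derived promoters from CAGE clusters, TFBS proximity, TE overlap
    and promoter containment; subfamily-normalised methylation, DNase
    sensitivity and dual-luciferase statistics; and a fully seeded
    synthetic-data generator emulating every input, so the complete
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
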