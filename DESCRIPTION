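Package: retinotarget
Title: Integrative Prioritization of Retinoid-Responsive Transcription
    Factor Target Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative multi-omic pipeline for nominating
    transcription-factor target genes that drive drug response in cancer
    stem-like (tumor-repopulating) cells. Combines fuzzy c-means
    clustering of dose-response expression profiles, ChIP-Seq peak
    filtering and promoter assignment, Pearson co-expression network
    degree analysis, pathway-burden scoring and a four-criterion
    lexicographic priority ranking, together with H3K27ac super-enhancer
    calling by rank-curve cutoff and dose-response pharmacology (4PL
    IC50 fitting and the Chou-Talalay combination index). Ships a
    synthetic-data generator with planted ground truth so every stage is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
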