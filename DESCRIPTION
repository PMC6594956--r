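Package: keescan
Title: H3K79me2/3-Marked Enhancer Classification and Differential
    Capture-C Interaction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies putative enhancers into H3K79me2/3-marked enhancer
    elements (KEEs) and non-KEEs from histone-modification peak calls,
    computes spike-in (ChIP-rx) normalization factors, tests enhancer-promoter
    Capture-C interactions for differential contact between control and
    DOT1L-inhibited conditions with an exact paired signed-rank test and
    Holm-Bonferroni correction, and provides the integration statistics
    linking enhancer class to transcriptional and chromatin-accessibility
    change. Includes a seeded synthetic-data generator that emulates the
    statistical structure of the sequencing inputs, with a ground-truth
    manifest for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    stats,
    utils,
    jsonlite,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
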