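Package: chromatlas
Title: Chromatin-State Segmentation and Tissue-Specific Enhancer Modules
    for Multi-Tissue Epigenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds regulatory-element atlases from multi-tissue histone-mark
    and chromatin-accessibility data. Provides Poisson-background signal
    binarization, a multivariate Bernoulli-emission hidden Markov model
    (Baum-Welch learning, Viterbi and posterior decoding) for chromatin-state
    segmentation, rule-based functional state naming with TSS-neighbourhood
    enrichment, tissue-specific strong-enhancer (EnhA) module calling via a
    binary cross-tissue overlap matrix, TAD-based enhancer-to-gene linking,
    and motif/term enrichment with exact hypergeometric tests. A seeded
    synthetic multi-tissue epigenome generator with planted ground truth makes
    the whole pipeline testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    methods,
    withr,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
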