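Package: activTag
Title: Predicting Enhancer-Driven Activation of Genes Flanking T-DNA
    Insertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling whether a gene flanking a T-DNA
    activation-tag insertion (carrying a CaMV 35S enhancer tetramer) is
    transcriptionally activated. Extracts three strand-aware sequence
    regions around each gene/insertion pair (the 1 kb promoter, the
    enhancer-to-start-codon interval and its 301 bp central window),
    encodes them with k-mer counts, position-weight-matrix motif scans,
    reduced dinucleotide physicochemical properties and CpG-island
    statistics, weights the encodings by a distance-based logistic model
    of activation probability, and stacks per-feature kernel classifiers
    under a Gaussian naive-Bayes integrator. Includes a synthetic
    activation-tagging study generator, cross-validation and
    exchange-testing protocols, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    e1071,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
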