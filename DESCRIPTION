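Package: teploop
Title: Machine-Learning-Guided Design of Translation-Enhancing Tetrapeptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for descriptor-based modelling and iterative design of
    N-terminal tetrapeptides that alleviate SecM arrest-peptide ribosome
    stalling in Escherichia coli. Provides enumeration of the 160,000-member
    tetrapeptide space and its NNK codon library, QSAR featurization with the
    Z-, T-, ST- and VHSE-scale amino-acid descriptors plus an mRNA ensemble
    free-energy feature from a built-in partition-function backend,
    cross-validated random-forest and gradient-boosting regression of
    SKIK-normalized fluorescence activity, diversity-aware candidate
    selection, an iterative train-score-select-measure design loop, sequence
    logo and dipeptide adjacency summaries, flank-anchored extraction of
    randomized regions from amplicon reads, and a synthetic activity
    landscape that stands in for cell-free protein synthesis measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    ranger,
    xgboost,
    jsonlite,
    yaml,
    Biostrings,
    BiocGenerics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
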