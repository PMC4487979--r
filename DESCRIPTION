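Package: kmerTax
Title: K-mer Based Genus Classification of 16S rRNA Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Word-count (K-mer) classifiers for assigning 16S rRNA gene
    sequences to genera: a presence/absence naive Bayes classifier in the
    style of the RDP classifier, a frequency-based multinomial naive Bayes
    classifier, a Markov transition-probability classifier, a
    nearest-neighbour classifier on multinomial K-mer profiles, and a
    nearest-neighbour classifier preprocessed by partial least squares
    (PLS) dimension reduction. Includes a round-robin 10-fold
    cross-validation benchmarking harness with read-length fragmentation,
    singleton-aware error summaries, error breakdowns by genus size,
    fragment position and method overlap, and a synthetic labelled-community
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
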