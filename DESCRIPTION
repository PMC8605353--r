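Package: rbpsites
Title: Discovery and Prediction of RNA-Binding Protein Binding Sites from
    Cross-Linking Peak Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Anchors statistically enriched, mismatch-tolerant k-mer "prime
    motifs" in cross-linking (CLIP-seq style) peak sequences using a
    Burrows-Wheeler transform / FM-index inexact search, derives contextual
    features from the 75-base flanks around the anchored motif (positional
    dinucleotide window densities, mismatch-tolerant pentamer and heptamer
    positional probabilities), detects co-occurring secondary motifs, builds
    balanced positive/negative instance sets, and trains gradient-boosted-tree
    and feed-forward neural network classifiers that separate bound from
    unbound motif-bearing regions. Fitted models scan new sequences for
    binding sites. A synthetic planted-motif data generator makes every stage
    testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    xgboost,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
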