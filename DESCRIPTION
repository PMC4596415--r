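Package: dectico
Title: Alignment-Free Metagenomic Sample Classification with Dynamic
    Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Supervised, alignment-free classification of metagenomic
    samples from raw sequencing reads.  Per-sample feature vectors are
    built from the intrinsic correlation of oligonucleotides (ICO) --
    junction ratios and average mutual information between the two
    consecutive parts of every k-mer split -- or from plain k-mer
    composition.  Features are ranked by kernel partial least squares and
    selected dynamically over a user-defined descending ladder, training a
    support vector machine and recording leave-one-out cross-validation
    accuracy at every rung; the classifier with maximal accuracy and
    fewest features is retained.  Includes stability and generality
    evaluation protocols (repeated subsampling, F1-measure, paired
    t-tests) and a Markov-chain community simulator for generating
    two-class synthetic read sets with controllable between-class
    divergence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
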