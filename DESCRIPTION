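Package: hiertax
Title: Hierarchical Alignment-Free Taxonomic Classification of
    Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Alignment-free, genetic-marker-free taxonomic classification of
    genomes and metagenome-assembled genomes (MAGs) by hierarchically
    structured local classification.  DNA sequences are represented as
    chaos-game k-mer frequency vectors (FCGR); one quadratic-kernel support
    vector machine is trained per parent taxon of a GTDB-style taxonomy, and
    per parent-child stopping thresholds learned from cross-validated
    training confidences turn low-confidence predictions into partial
    classification paths instead of forced (and likely wrong) species calls.
    Includes genome-level evaluation metrics for partial classification
    paths (constrained, absolute and weighted accuracy, and complete
    classification rate), a deterministic synthetic-corpus generator for
    benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    e1071,
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
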