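Package: cladescan
Title: Multi-Source Protein Domain Annotation of Short Metagenomic Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Annotates protein domains on short metagenomic and
    metatranscriptomic reads using a library of per-domain consensus models
    (SCMs) and clade-centered models (CCMs). Per-domain two-dimensional
    gathering thresholds over (bit-score, mean-bit-score) are learned with a
    discrete naive Bayes classifier trained on simulated positive domain
    fragments and algorithmically generated negative decoy sequences
    (2-mer shuffles, reversals and order-3 Markov chains). Raw search hits
    from HMMER domtblout files, PSI-BLAST tabular files or a built-in
    position-specific scoring matrix scanner are passed through a
    three-stage selection pipeline (same-domain redundancy removal,
    probability filtering, greedy overlap resolution) to produce
    non-overlapping per-read domain architectures, followed by GO-based
    functional abundance profiling. Includes a synthetic-data generator for
    domain families, model libraries and read sets with planted fragments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
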