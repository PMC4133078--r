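Package: barcodeFdr
Title: Barcode Detection and Demultiplexing in Noisy Long Reads by
    Tail-Area False Discovery Rate Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and demultiplexes DNA-barcoded reads in noisy long-read
    sequencing data such as PacBio continuous long reads, where the barcode
    position is unknown and many reads start inside the genomic insert.
    Reads are scored by their minimal Sequence-Levenshtein distance to a
    reference barcode (or barcoded-primer) set; a two-component mixture of
    simulated barcoded and orphaned reads is fitted to the empirical distance
    histogram by an evolutionary search, and a distance threshold is chosen
    by controlling the tail area-based false discovery rate. Also provides
    error-correcting [l,d] barcode set design, a PacBio-like read simulator
    with insertion/deletion/substitution error ratios, precision/sensitivity
    tables and per-sample demultiplexing with barcode trimming.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
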