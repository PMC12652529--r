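Package: nanobrdu
Title: BrdU Basecalling from Nanopore Event Signals with Bidirectional GRU Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects the thymidine analog BrdU (5-bromo-2'-deoxyuridine) in Oxford
    Nanopore R9 sequencing data at single-nucleotide resolution. Provides a seeded
    5-mer pore-model simulator that emulates resquiggled event tables with
    BrdU-induced current shifts, feature and label engineering for 5-mer windows,
    a three-layer bidirectional GRU classifier over the five base classes
    (A, BrdU, C, G, T) trained with early stopping, read-level BrdU substitution
    rate estimation with bimodal-mixture relabeling, multiclass and binary
    performance metrics including the area under the precision-recall curve, and
    an orchestrated three-model data-augmentation workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
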