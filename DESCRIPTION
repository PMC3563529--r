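Package: barcodeGap
Title: Barcode-Gap Analysis of DNA Barcode Efficacy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the efficacy of a DNA barcode marker by the
    barcode-gap probability of correct identification (PCI). Implements
    affine-gap pairwise DNA alignment (global, semi-global and local),
    extraction of the implied pairwise alignments of a multiple sequence
    alignment, alignment and evolutionary sequence distances (p, JC69, K2P,
    F81, TN93), per-species barcode-gap determination, PCI estimation with
    Wilson score confidence intervals, and contingency statistics for
    comparing data sources and expert morphological identification. A
    seeded simulator of ITS-like datasets with controlled intra- and
    interspecific divergence supports end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
biocViews: Alignment, SequenceMatching, Classification, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
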