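Package: coibarcode
Title: DNA Barcoding Assessment of COI Reference Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing cytochrome oxidase subunit I (COI) DNA
    barcode reference libraries of the kind assembled for species-rich
    faunas. Implements sequence quality control (length, reading-frame and
    stop-codon screening, divergence outliers), p and Kimura 2-parameter
    pairwise distances with pairwise deletion, neighbor-joining tree
    estimation with nonparametric bootstrap support, monophyly scoring of
    genera and families, distance-threshold delimitation of candidate
    species from well-supported sister pairs, taxon-subsampling and
    mini-barcode simulation experiments, and a coding-sequence simulator
    that generates taxonomically structured COI-like test data with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape (>= 5.0),
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
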