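Package: nucwrap
Title: Sequence-Dependent Nucleosome Wrapping Energies from a
    Coarse-Grained Rigid-Base DNA Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes sequence-dependent nucleosome wrapping energies and
    log probability densities of optimal nucleosomal DNA configurations.
    A Gaussian rigid-base-plus-phosphate model of double-stranded DNA is
    assembled from a dimer-step parameter set (ground state and banded
    stiffness matrix), and the model energy is minimised under elastic
    constraints that pin the histone-bound phosphates to reference
    positions. Includes CpG accounting and symmetric cytosine
    (hydroxy)methylation over an extended alphabet, dinucleotide-preserving
    sequence shuffling, CpG-island by non-methylated-island genomic region
    classification, 147-bp window scans, synthetic fixture generators for
    parameter sets and nucleosome structure ensembles, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
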