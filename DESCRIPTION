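Package: extrusim
Title: Stochastic Simulation of DNA Loop Extrusion and Contact-Matrix Tooling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fast stochastic simulation of DNA-DNA contacts generated by
    cohesin-mediated loop extrusion on a one-dimensional chromatin lattice.
    Loop-extrusion factors bind, extrude and release DNA; CTCF-like extrusion
    barriers are modeled as two-state (Bound/Unbound) Markov chains with a
    blocking direction. Contacts are accumulated in banded sparse matrices and
    written as single-resolution cooler files. Companion tooling transforms
    contact matrices with a difference-of-Gaussians filter, scores stripe and
    dot similarity between matrices, and fits barrier parameters against a
    reference matrix, either uniformly via Gaussian-process Bayesian
    optimization or per barrier with a (mu, lambda) evolution strategy and an
    island model.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    rhdf5,
    jsonlite,
    lhs,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    IRanges,
    GenomeInfoDb
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
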