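Package: evofix
Title: Exact Fixation Probabilities and Selection Regimes of the Moran
    Process on Graphs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the Birth-Death Moran process on undirected graphs:
    exact (arbitrary-precision rational) and numeric fixation probabilities,
    exact rational-function fixation curves obtained by evaluation and
    interpolation, automorphism-orbit reduction of the subset state space,
    classification of graphs into isothermal, amplifier and suppressor
    regimes with exact isolation of regime transitions, enumeration of all
    small connected graphs up to isomorphism, and a batch census pipeline
    with barcode exports.  Includes constructors for the graph families used
    in the study of suppression mechanisms (ell-graphs, friendship cycles,
    stars and ribbons) and a Monte-Carlo trajectory simulator used as an
    independent stochastic check of the solvers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: GNU MP library (libgmp, libgmpxx)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
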