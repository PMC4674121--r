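Package: cachalot
Title: Morphological Parsimony and Body-Size Evolution in Sperm Whales
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the comparative analysis of fossil and living sperm
    whales (Physeteroidea) from discrete morphological characters and cranial
    measurements. Implements Fitch parsimony for unordered multistate
    characters with missing data and polymorphism (generalized to
    multifurcating trees), heuristic tree search by random-addition sequences
    with tree-bisection-reconnection branch swapping, strict consensus,
    nonparametric bootstrap and Bremer decay clade support, squared-change
    parsimony mapping of continuous traits such as condylobasal length onto a
    phylogeny, and a two-method allometric pipeline estimating condylobasal
    length and total body length from antorbital notch width. Includes NEXUS
    and Newick readers and writers and simulators for Mk-style discrete
    character matrices and bivariate allometric reference data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
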