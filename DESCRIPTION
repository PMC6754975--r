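Package: maxpars
Title: Maximum Parsimony Analysis of Discrete Morphological Character Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cladistic analysis of discrete morphological character
    matrices under equal-weights maximum parsimony: NEXUS/TSV matrix input and
    output with missing and inapplicable tokens, Fitch tree-length computation
    for unordered multistate characters, two-step heuristic tree search
    (random-addition stepwise construction followed by tree
    bisection-reconnection branch swapping) with an exhaustive-search oracle
    for small instances, strict consensus and outgroup rooting, ensemble
    consistency and retention indices, ACCTRAN ancestral-state reconstruction
    with synapomorphy and homoplasy classification, and an Mk-style simulator
    of morphological matrices with controllable homoplasy, missingness and
    inapplicability. Ships the character matrix of a published phylogenetic
    analysis of microphthalmid annelids as a worked, validated example and a
    replication pipeline for its results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
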