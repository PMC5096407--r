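Package: morphparsimony
Title: Maximum Parsimony Analysis of Morphological Character Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for cladistic analysis of discrete morphological data:
    reading and writing character matrices (NEXUS, TNT and CSV dialects,
    with missing, inapplicable, polymorphic and variable cells), Fitch
    parsimony scoring of unordered multistate characters, heuristic tree
    search by random addition sequences with NNI/SPR/TBR branch swapping,
    exact branch-and-bound search, parsimony ratchet, implied weighting,
    character jackknife support, strict consensus, homoplasy diagnostics
    (tree length, consistency and retention indices, per-character fits),
    Mk-model simulation of character matrices on known trees, and an
    executable dichotomous identification key for Pseudobranchiomma
    (Sabellidae). Ships a published 26-taxon and an 11-taxon sabellid
    matrix as fixtures and numbered analysis scripts reproducing the
    morphology-only results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
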