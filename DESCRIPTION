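Package: superrec
Title: Super-Reconciliation of Gene Trees Under Segmental Duplication and Loss
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers evolutionary histories of syntenies (ordered blocks of
    neighboring genes) by reconciling a set of gene trees with a species
    tree under a model of segmental duplications and segmental losses.
    Provides the consistency checks (gene-order consistency via the
    precedence graph, rooted-triplet tree consistency and BUILD supertree
    construction), the exact exponential-time dynamic program over ancestral
    gene orders, the polynomial-time unordered variant over gene contents,
    brute-force oracles for validation at small scale, and a five-parameter
    simulator of segmental duplication-loss histories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
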