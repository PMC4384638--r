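Package: phylofam
Title: Phylogenetic Comparative Analysis of Gene-Family Size and Life History
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether the size of a gene family covaries with
    life-history traits across species while accounting for shared ancestry.
    Implements Newick tree handling, phylogenetic variance-covariance matrices
    with Pagel's lambda transformation, Felsenstein's independent contrasts
    with regression through the origin, phylogenetic generalized least squares
    (PGLS) with fixed or maximum-likelihood lambda, a reproduction pipeline for
    a 14-mammal study of CD33-related Siglec (and control family) gene counts
    versus maximum lifespan and body mass, and a Brownian-motion trait
    simulator used to validate every estimator by parameter recovery and
    null calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    ape,
    nlme,
    phytools,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
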