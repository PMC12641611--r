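Package: opals
Title: Orthonormal Pairwise Logratio Coordinate Systems for Compositional Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-dimensional compositional data through
    pairwise logratios embedded in orthonormal (or orthogonal) logratio
    coordinate systems. Implements the OPALS construction, which uses a
    symmetric diagonal Latin square (a 1-factorization of the complete graph)
    to pack D/2 non-overlapping pairwise logratios into each of D-1 coordinate
    systems, jointly covering all D(D-1)/2 pairwise logratios of a D-part
    composition. Includes the standard logratio transforms (alr, clr, pivot,
    balances from sequential binary partitions, backwards pivot coordinates),
    partial least squares and ordinary least squares modelling over all
    pairwise logratios with bootstrap-standardized coefficients and
    significance screening, per-part aggregation of significant logratios,
    a simplex-normal data simulator, and delimited-text input/output with a
    minimum-nonzero part filter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    optparse,
    jsonlite
Config/testthat/edition: 3
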