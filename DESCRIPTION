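Package: bandpop
Title: Dominant-Marker Band Matrix Analysis for Population Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the complete analysis of dominant molecular-marker band
    matrices (SSR, IT-ISJ, RAPD, ISSR and similar presence/absence data):
    marker-efficiency statistics (polymorphic information content, average band
    informativeness, effective multiplex ratio, marker index), dominant-marker
    diversity statistics under Hardy-Weinberg equilibrium (Na, Ne, Nei's gene
    diversity, Shannon's index with intra/inter-group partitioning), Dice
    dissimilarity and unweighted neighbor-joining trees with bootstrap clade
    support, and one-way distance-based analysis of molecular variance (AMOVA)
    with permutation tests.  Includes a Balding-Nichols band-matrix simulator
    with known truth for parameter-recovery testing, and a pipeline that
    reproduces the standard report tables of a dominant-marker diversity study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
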