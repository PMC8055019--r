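Package: hawkdovenet
Title: Hawk-Dove Games with Power Asymmetry on Dynamic Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Agent-based simulation of repeated hawk-dove games of conflict
    under power asymmetry. Agents learn both strategies and interaction
    partners through Roth-Erev reinforcement with discounting and trembles.
    Three model variants are provided: random interaction on a static uniform
    network, partner choice on a learned dynamic network, and partner choice
    coupled with ranks that are periodically recomputed from accumulated
    payoffs. The package includes closed-form results for the per-rank
    expected game and the dominance-solvability phase transition, together
    with the summary statistics used to characterise outcomes: strategy and
    convention classification, network centralization, conflict fractions,
    rank-cycle length, welfare, and the Gini index of accumulated payoffs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
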