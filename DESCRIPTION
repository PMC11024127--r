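Package: tcellsim
Title: Agent-Based Multi-Scale Stochastic Simulation of T-Cell Lineage
    Commitment
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic multi-scale simulator of early T-cell lineage
    commitment. A six-species transcriptional gene regulatory network
    (Runx1, Tcf7, Gata3, PU.1, the Bcl11b-opposing function X, and Notch
    signalling) is simulated with the Gillespie algorithm using
    Shea-Ackers regulation functions; its output drives an extended
    Gillespie model of a 500-site three-state Bcl11b regulatory region;
    proliferating cells carrying both levels form lineage trees over a
    120 hour colony horizon. Every cell of a simulated colony is
    classified by its relation to Bcl11b-open (committed) descendants
    into last-common-ancestor (LCA) categories, enabling analysis of
    commitment-decision inheritance. In silico knockdown protocols,
    per-category expression statistics, Newick/NHX lineage-tree
    import/export, and a command-line driver are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    deSolve,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
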