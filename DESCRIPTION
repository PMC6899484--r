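Package: nmainc
Title: Inconsistency Diagnostics for Fixed-Effect Network Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for locating and testing inconsistency in contrast-based
    network meta-analysis under a fixed-effect two-stage model. Implements the
    decomposition of Cochran's Q into within-design heterogeneity and
    between-design inconsistency, the net heat matrix obtained by detaching
    each design via design-matrix augmentation, Bucher's adjusted indirect
    comparison test for three-treatment loops, frequentist node-splitting,
    closed-form expressions for the net heat statistics in triangle and radial
    networks, and a simulation engine for radial networks with one inflated
    design that demonstrates how the net heat statistic masks inconsistency as
    treatment loops are added. Includes a command-line interface and packaged
    design-level example networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
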