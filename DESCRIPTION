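Package: mitonet
Title: Spatial Stochastic Simulation of Mitochondrial Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulation of mitochondrial fusion, fission,
    selective autophagy (mitophagy), population-limited biogenesis,
    oxidative damage, and cytoskeletal transport of circular mitochondria
    in a two-dimensional cell. Each mitochondrion carries a vector of
    discrete health units; fission exchanges a fixed number of randomly
    chosen units between the separating partners, generating the health
    asymmetry that selective autophagy exploits. The package provides the
    fixed-time-step stochastic engine (compiled core), ensemble runners
    with reproducible seeding, steady-state and fusion-frequency metrics,
    network-component statistics, and config-driven parameter-scan
    experiments (exchange-count, threshold-coupling, density, motility,
    rate-cap, and health-unit-discreteness scans), together with a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
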