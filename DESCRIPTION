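Package: phagesim
Title: Individual-Based Simulation of Lytic Phage-Bacteria Coevolution in a Chemostat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic individual-based model of coevolving lytic
    bacteriophages and their bacterial hosts in a phosphorus-limited
    chemostat. Hosts carry a heritable nutrient-affinity gene and viruses
    carry host-range and adsorption genes; infection is governed by
    trade-off based or random compatibility and virulence kernels.
    Provides the simulation engine (Rcpp), ensemble replication, parameter
    sweeps and long-term closed/open factorial experiments, Shannon-entropy
    trait-diversity time series, YAML configuration loading, and tidy CSV
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
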