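Package: autocc
Title: Auto-Logistic Multi-Season Occupancy Models for Avian Predators in
    Conifer-Expanded Shrubland
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and Bayesian analysis of dynamic (multi-season)
    occupancy of generalist avian predators along a juniper-expansion
    gradient.  Provides a synthetic-data generator (clustered tree-cover
    landscapes, stratified 800-m survey transects, repeated-visit detection
    histories with a mid-series removal treatment, and prey layers),
    multi-scale landscape covariate extraction (buffer percent cover, cover
    category proportions, cliff distance from a DEM slope threshold,
    distance-to-feature, nearest-neighbour clustering, terrain roughness),
    an auto-logistic multi-season occupancy model with the latent state
    marginalised by a two-state forward recursion, adaptive random-walk
    Metropolis sampling with split R-hat diagnostics, derived yearly
    habitat-use summaries, PSIS-LOO model comparison, Freeman-Tukey
    posterior predictive checks, and a staged model-selection workflow
    (detection screening, spatial-scale screening, habitat-structure and
    prey candidate sets).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
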