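Package: hlsim
Title: Simulation of Tumor-Microenvironment Dynamics in Hodgkin Lymphoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A stock-and-flow simulator of the interaction between three
    tumor-cell sub-compartments (cancer stem cells, transit amplifying
    cells, mature tumor cells) and three bystander compartments (helper,
    killer and regulatory cells) in the Hodgkin lymphoma
    micro-environment. Provides fixed-step Euler integration with the
    published update semantics, pulse-scheduled cytotoxic and
    immunotherapeutic interventions, a registry of named scenario
    presets, outcome classification of simulated trajectories, and
    search utilities for treatment-timing windows and minimal effective
    doses, together with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
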