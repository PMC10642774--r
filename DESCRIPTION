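Package: CarbonTransit
Title: Transit-Time and Age Distributions for Compartmental Carbon-Cycle
    Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for linear compartmental models of the terrestrial
    carbon cycle. Computes closed-form age and transit-time distributions
    (phase-type) for autonomous systems at equilibrium, backward
    transit-time distributions for non-autonomous systems via the
    state-transition operator, radiocarbon (Delta-14C) signatures of pools
    and of the respiration flux, and homogeneity diagnostics of the
    transit-time distribution. Includes the five-pool global terrestrial
    model of Emanuel and co-workers with twentieth-century CO2 and
    temperature forcing, synthetic-data generators, and an independent
    Monte-Carlo particle oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    deSolve,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
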