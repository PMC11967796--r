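Package: stepemul
Title: Centrifugal Step Emulsification Modelling and Droplet Digital Assay Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Closed-form hydraulics and a data-driven predictive model for
    droplet generation by centrifugal step emulsification. Computes driving,
    capillary and hydraulic-resistance pressures for rectangular
    microchannels in a rotating frame, simulates sample-reservoir depletion,
    fits per-acceleration exponential laws linking a connection-tube
    resistance factor to droplet diameter, and predicts droplet diameter and
    generation frequency. Includes droplet pre-design under monolayer tiling
    constraints (area budgets, admissible diameter windows, reverse
    engineering of generation conditions) and the digital-assay statistics
    used downstream: fluorescence thresholding with drift-robust local
    classification, Poisson concentration estimation, dilution linearity,
    limit of detection and minimum inhibitory concentration. Seeded
    synthetic-data generators emulate the structure of multi-condition
    emulsification datasets and bimodal droplet fluorescence populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
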