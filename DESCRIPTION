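Package: ventsplit
Title: Lumped-Parameter Simulation of Single-Ventilator Dual-Patient Ventilation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Electrical-analogue (resistor-capacitor network) simulation of one
    pressure-controlled ventilator supporting two patients through a T-piece
    splitter. Provides the standard splitter and a modified splitter with inline
    variable flow restrictors on the inspiration arms and one-way valves on the
    expiration arms, a switched-network solver with ideal check valves, per-cycle
    tidal-volume and achieved-PEEP metrics, a closed-form steady-state oracle for
    single resistor-capacitor branches, and calibration routines that titrate peak
    inspiratory pressure and restrictor resistances to equalize or independently
    adjust tidal volumes in patients with mismatched respiratory compliance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
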