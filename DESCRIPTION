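Package: cetpkpd
Title: Population Pharmacokinetic-Pharmacodynamic Modelling of a CETP Inhibitor
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Sequential population pharmacokinetic-pharmacodynamic (PK-PD) model
    system for an oral cholesteryl ester transfer protein (CETP) inhibitor:
    dose- and time-dependent relative bioavailability feeding a five-compartment
    Erlang transit absorption chain and three-compartment linear disposition;
    indirect-response (turnover) models linking plasma concentration to CETP
    activity and CETP activity to HDL-C and LDL-C; a synthetic phase-I
    multiple-ascending-dose trial generator with log-normal inter-individual
    variability and additive/proportional residual error; staged pooled
    least-squares estimation (PK, then CETP with individual PK fixed, then
    lipids with individual CETP fixed) with bootstrap intervals and visual
    predictive checks; and fixed-effects dose-selection simulation against
    40 percent lipid-change targets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    Matrix,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
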