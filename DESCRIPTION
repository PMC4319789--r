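Package: mcncycle
Title: Cell-Cycle Dynamics of the Fission Yeast Minimal Cdk Network
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic and stochastic simulation of a minimal
    cyclin-Cdk control network for the fission yeast cell cycle, in which
    a single Cdc13-L-Cdc2 fusion protein (MPF) drives both DNA replication
    and mitosis.  Provides the ordinary differential equation model with
    Goldbeter-Koshland ultrasensitive regulation of Wee1, Cdc25 and the
    APC, growth-division cycling with threshold-based phase
    classification, one-parameter bifurcation analysis over cell mass
    (steady-state branches, stability, SNIC detection, oscillation
    envelopes), a Gillespie stochastic version with per-birth parametric
    noise, genotype presets for the mutant strains built on the minimal
    network, and report generators for phenotype tables, inhibitor-reset
    protocols and Wee1 titration scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Config/testthat/start-first: model, parameters, events, simulate, stochastic,
    bifurcation, report
RoxygenNote: 7.3.3
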