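Package: chemloop
Title: Closed-Loop Chemical Procedure Execution, Analysis and Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale engine for closed-loop chemical synthesis
    development. Provides a structured-text dialect for versioned chemical
    procedures with unit-carrying quantities, an interpreter with
    sensor-feedback dynamic steps (temperature-gated addition,
    colour-gradient endpoint detection, liquid-sensor transfers), a
    simulated laboratory backend with reaction response surfaces and
    synthetic NMR/HPLC/Raman data, an analytical processing chain
    (zero-filling, apodization, Fourier transform, asymmetric-least-squares
    baseline correction, peak picking, integration), spectrum-derived
    optimization objectives (area ratios, purity, desirability, conversion,
    novelty), staged Gaussian-process sequential model-based optimization
    alongside random search, Latin hypercube designs and a genetic
    algorithm, a resource-constrained parallel scheduler with ordered
    locking, and a campaign driver with an append-only database, restart
    and exploration-to-optimization discovery pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    Matrix,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
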