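Package: bmusim
Title: Osteocyte-Driven Targeted Bone Remodeling Simulator
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates a single event of targeted bone remodeling at the
    scale of a basic multicellular unit (BMU). The model is a five-variable
    nonlinear ordinary differential equation system for the osteocyte,
    pre-osteoblast, osteoblast and osteoclast populations and bone volume,
    written in the power-law (biochemical systems) formalism, with
    sclerostin inhibition of Wnt signaling represented by a thresholded
    osteocyte-deficit gate. Provides stiff-capable integration with
    remodeling-cycle detection, steady-state bone volume analysis,
    parameter sweeps with normal-remodeling contour root-finding,
    calibration of the bone-formation rate, and piecewise-constant
    time-dependent dosing for anti-sclerostin treatment scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
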