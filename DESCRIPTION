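Package: flashros
Title: Radiolytic Oxygen Depletion and ROS Kinetics for FLASH Radiotherapy Survival Modelling
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Mechanistic simulator of differential tumor and normal-tissue
    response to ultra-high-dose-rate (FLASH) versus conventional radiotherapy
    in a multicellular spheroid. Solves the steady-state oxygen diffusion
    problem with a free anoxic-core boundary, models radiolytic oxygen
    depletion during the pulse, evolves the FLASH-minus-conventional
    difference in reactive oxygen species by a linear kinetic ODE, and
    computes per-radius and volume-aggregated surviving fractions with an
    oxygen-enhancement-ratio modified linear-quadratic model plus a sigmoid
    oxidative-stress term. Includes closed-form solvers cross-checked by
    finite-difference and Runge-Kutta oracles, named scenario presets, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    Matrix,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    lhs,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
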