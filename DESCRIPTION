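Package: cordicfhn
Title: Multiplierless CORDIC Emulation of the FitzHugh-Nagumo Neuron
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and validation toolkit for a shift-add (CORDIC)
    approximation of the FitzHugh-Nagumo spiking neuron, as used in
    multiplierless digital hardware. Provides a linear-mode CORDIC
    multiplier and two-stage cube with real and bit-accurate Q8.8
    fixed-point backends, continuous (adaptive Runge-Kutta) and discrete
    (forward Euler) simulators for the original and CORDIC models,
    equilibrium and stability analysis, bifurcation diagrams and maximum
    Lyapunov exponent estimation under sinusoidal drive, seeded random
    spiking networks with raster comparison, and the error and hardware
    cost metrics used to compare the two models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
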