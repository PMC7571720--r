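Package: sarcodyn
Title: Reduced Markov Models of Cardiac Sarcomere Force Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Biophysically detailed, Monte-Carlo-free models of active force
    generation in cardiac sarcomeres.  A continuous-time Markov chain of
    troponin/tropomyosin regulatory units with nearest-neighbour cooperativity,
    coupled to two-state crossbridge cycling, is reduced to four tractable
    models: a mean-field triplet model and a spatially explicit per-unit model,
    each in a distribution-moments (ODE) and a strain-density (PDE) variant.
    The package ships calibrated parameter presets for room-temperature rat
    and body-temperature human cardiomyocytes, virtual-experiment protocols
    (steady-state force-calcium and force-length curves with Hill fits,
    isometric twitches, force-velocity curves, fast length steps), an exact
    small-chain master-equation and Gillespie oracle used to validate the
    closures, and a staged calibration pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    minpack.lm,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
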