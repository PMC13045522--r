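Package: valvejet
Title: Printability Analysis for Microvalve-Based Droplet Bioprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolbox for assessing bioink printability in microvalve-based
    droplet bioprinting. Fits power-law shear-thinning viscosity models to
    rheometer flow curves with inverse-square weighted Levenberg-Marquardt
    least squares, computes the dimensionless jetting numbers (Weber,
    Reynolds, Ohnesorge, Froude, Z, splash parameter, Bond), performs
    gravimetric per-drop volume calibration with acceptance rules, estimates
    ligament velocity and geometry from stroboscopic displacement sweeps,
    evaluates the closed-form fully developed power-law pipe flow in the
    nozzle (velocity, shear-rate and apparent-viscosity profiles with wall
    values), classifies jetting regimes against the canonical 1 <= Z <= 10
    printable band, recommends actuation-frequency bands, and builds
    printability-map datasets with ggplot2 methods. Seeded synthetic-data
    generators reproduce every input format for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
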