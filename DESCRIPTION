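Package: dermasim
Title: Virtual Franz-Cell Release and Skin Permeation Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A mechanistic virtual laboratory for dermal drug delivery. Simulates
    in vitro release testing (IVRT) of semisolid formulations through an inert
    porous membrane and in vitro permeation testing (IVPT) through a multi-layer
    skin barrier with an explicit brick-and-mortar stratum corneum, including
    Franz diffusion cell receptor sampling and replenishment dynamics. Donor
    vehicles are modelled mechanistically: creams as two-phase oil-in-water
    emulsions, ointments as solid-particle suspensions with Nernst-Brunner
    dissolution kinetics, and simple solutions. Provides derived Franz-cell
    metrics (cumulative permeation per area, steady-state flux, lag time,
    permeability coefficient, skin-layer deposition, recovery), per-timepoint
    one-way ANOVA group comparison, a seeded synthetic replicate-data generator,
    and a two-stage calibration pipeline that fits release-model parameters to
    IVRT data before fitting skin transport parameters to IVPT data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
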