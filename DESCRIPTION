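Package: dorsaflow
Title: Dorsal Cell Mechanics from Microfluidic Bead Force Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microfluidic force measurements on the
    dorsal (upper) surface of adherent cells probed with ligand-coated
    micron-scale beads in a shallow rectangular flow channel. From bead
    trajectories the package computes dorsal traction forces transmitted
    through receptor-ligand bonds, whole-cell viscoelastic parameters via a
    Kelvin-Voigt four-element creep-compliance fit, and multivalent bond
    rupture forces under a step-wise flow ramp. The hydrodynamic force
    calibration uses a semi-analytic laminar channel-flow profile with
    Lagrangian particle advection (Schiller-Naumann drag), wall-corrected
    Stokes drag, and a logistic force-distance fit. Includes synthetic
    trajectory and image-stack generators with ground truth for every
    measurement mode, a minimal spot detector and linker, ggplot2 plotting
    methods, and tidy()/glance() accessors for fitted objects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
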