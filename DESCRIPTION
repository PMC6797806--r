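Package: boneadapt
Title: Strain-Energy-Driven Bone Remodeling Simulation in 2D Tooth-Mandible Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Iterative simulation of load-adaptive trabecular bone remodeling
    in two-dimensional tooth-mandible cross sections. Generates parametric
    synthetic geometry (teeth with enamel, dentin, pulp, cementum and PDL,
    gingiva, cortical shell and trabecular fill) on a structured quadrilateral
    mesh, solves plane-stress linear elasticity under chewing/biting loads,
    and evolves the apparent trabecular density with a strain-energy-density-
    per-unit-mass stimulus rule featuring an equilibrium (lazy) zone,
    saturated change rates and density clamps. Includes parametric sweep
    drivers (boundary conditions, initial density, reference stimulus,
    equilibrium-zone width), stability diagnostics for checkerboard patterns,
    YAML configuration, VTK/CSV/PNG output, and broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    readr,
    yaml,
    jsonlite,
    generics,
    stats,
    tools,
    utils,
    methods,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
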