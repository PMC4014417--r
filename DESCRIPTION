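Package: glidemech
Title: Biophysical Simulation of Bacterial Gliding Motility and Substrate Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A node-and-spring mechanical model of gliding Myxococcus xanthus
    cells used to discriminate between viscous and elastic motor-substrate
    coupling. Cells are flexible chains of circular nodes and rectangular
    spacers driven by distributed propulsion forces, with Stokes drag and,
    optionally, breakable elastic adhesion bonds to the substrate. The package
    simulates head-to-side cell-cell collisions and the associated parameter
    sweeps (adhesion stiffness, collision position, collision angle,
    robustness), quantifies orientation changes from tracked cell-pole
    coordinates including the spontaneous-turning correction, and implements a
    synthetic optical-trap force-clamp assay with exponential force-velocity
    fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    minpack.lm,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
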