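Package: scanseek
Title: One-Dimensional Scanning and Assembly of DNA Sensors on Stretched DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for single-molecule studies of
    proteins that scan along stretched DNA by one-dimensional diffusion and
    assemble into clusters. Provides a Brownian trajectory generator with
    reflecting nucleosome barriers and flow drift, kymograph rendering,
    mean-square-displacement diffusion estimation with drift correction,
    flow-cell hydrodynamics (plane-Poiseuille profile and wall-corrected
    Stokes drag), a Monte-Carlo model of pairwise target search on occupied
    DNA with an analytic first-passage oracle, cluster stoichiometry from
    single-fluorophore intensities, and nonlinear fits of bulk assembly
    kinetics and competition-binding curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
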