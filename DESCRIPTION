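Package: piezorbc
Title: Curvature Coupling and Spatial Organization of Piezo1 in Red Blood Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative machinery for studying how the mechanosensitive channel
    Piezo1 organizes on the red blood cell membrane. Builds a calibrated biconcave
    discocyte surface with principal and mean curvature fields, minimizes the
    Helfrich bending energy of the free membrane surrounding the curved Piezo dome
    in closed vesicles to obtain a curvature-coupling energy profile, and maps that
    profile through the Boltzmann distribution to a predicted Piezo1 surface
    density and dimple/rim enrichment. Also provides fluorescence spot detection
    with nearest-neighbour and complete-spatial-randomness statistics,
    single-particle-tracking analysis (time-averaged mean squared displacement,
    macroscopic and microscopic diffusion coefficients, confinement, dimple
    occupancy), exact optimal-transport colocalization curves with confidence
    bands, and seeded synthetic-data generators for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    minpack.lm,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
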