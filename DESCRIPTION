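Package: spimix
Title: One-Step Classification and Multi-Reconstruction for Mixed XFEL
    Single-Particle Diffraction Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for X-ray free-electron laser (XFEL) single-particle
    imaging when the injected sample is a mixture of species (for example a
    monomer/dimer/tetramer equilibrium or a partially dissociated complex).
    The package simulates photon-counting diffraction patterns from atomic
    models via analytic Gaussian-atom structure factors on the curved Ewald
    sphere, builds 3D diffraction-intensity templates from predicted
    structures, and runs a one-step template-aided algorithm that jointly
    classifies each pattern by species, determines its orientation by
    FFT-accelerated Pearson correlation against template slices in polar
    coordinates, and iteratively merges the classified patterns into one 3D
    diffraction intensity per species.  Evaluation utilities compute
    confusion matrices, geodesic orientation errors and resolution-shell
    correlation curves with the CC = 0.5 resolution criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
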