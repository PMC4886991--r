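Package: stillgrid
Title: Per-Image Spot-Finding Parameter Optimization for Still-Shot
    Serial Crystallography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Processing of still diffraction images from serial
    crystallography experiments, where per-image variability in spot
    shape and intensity defeats any single choice of spot-finding
    parameters.  For each image a grid of (minimum spot height, minimum
    spot area) parameter pairs is searched; every grid point runs a full
    spot-finding, target-cell indexing, lattice refinement, mosaic
    estimation and integration pipeline, and the best result is selected
    by a two-step heuristic based on the Ewald proximal volume (EPV), the
    reciprocal-space volume within which lattice points satisfy the
    diffraction condition for the fitted mosaic model.  Includes a
    synthetic still-image generator with known ground truth, SMV-format
    image input/output, beam recentering, beam-stop masking and blank-image
    triage, unit-cell Niggli reduction and hierarchical clustering of
    integrated images by crystal form, and run-level analytics (parameter
    heat maps, beam-center scatter, summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
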