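Package: holotrack
Title: Multi-Height Lensless Holographic Microscopy Reconstruction and Cell
    Migration Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for multiplexed lensless in-line
    digital holographic microscopy of live cell cultures. Provides
    angular-spectrum free-space propagation with point-source (spherical
    illumination) geometry, multi-height Gerchberg-Saxton phase retrieval with
    a positive absorption constraint for twin-image suppression, dark-field
    gradient autofocusing, fixed-threshold phase segmentation with physical
    area classification, globally optimal frame-to-frame cell tracking with
    windowed migration-speed statistics, and a physically consistent
    synthetic-hologram generator supplying ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
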