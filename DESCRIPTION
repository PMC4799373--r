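Package: microwound
Title: Morphometrics, Migration and Tension Analysis for 3D Microtissue Wound-Repair Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for microsurgically wounded 3D microtissues
    suspended between flexible cantilevers. Segments the tissue in calibrated
    time-lapse image stacks and measures gap morphometrics (area, centroid,
    moment-fitted ellipse, circularity, tissue width), fits linear closure
    kinetics and relative closure, detects and links nuclear trajectories and
    summarises migration directionality as windrose histograms, and converts
    cantilever-cap bead deflections into tissue tension via a calibrated spring
    constant. Includes a seeded synthetic scene generator with exact ground
    truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
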