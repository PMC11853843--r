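Package: hsiphantom
Title: SWIR Hyperspectral Target Detection and Spectral Unmixing on Tissue Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of short-wave infrared (900-1700 nm)
    hyperspectral reflectance images of tissue-mimicking phantoms.
    Provides a seeded synthetic phantom generator (collagen slabs,
    embedded lipid targets at depth, collagen concentration panels,
    and a sloped lipid wedge) with exact ground truth; constrained
    energy minimization (CEM) matched filtering for subpixel target
    detection with Otsu binarization and Tanimoto-index validation;
    linear spectral unmixing by unconstrained, sum-to-one, and fully
    constrained least squares (FCLS); ENVI-compatible cube input and
    output; and end-to-end validation experiments relating detection
    accuracy to target depth and abundance estimates to concentration
    and slope depth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
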