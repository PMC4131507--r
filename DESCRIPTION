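Package: lfac
Title: Partition-Based Fuzzy Active Contours with Local Intensity Information
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Region-based image segmentation for single-channel images with
    smooth intensity inhomogeneity. Implements a fuzzy active contour model
    whose region prototypes are spatially varying, Gaussian-kernel-weighted
    local means, evolved only inside an adaptively detected narrow band
    obtained by shadowed-sets three-way thresholding of the membership map.
    Includes the global-prototype fuzzy active contour baseline, a
    morphological narrow-band variant, the percentage-of-mislabelled-pixels
    accuracy score, and deterministic synthetic scene generators (intensity
    ramps, blurred boundaries, Gaussian and salt-and-pepper noise) with exact
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    stats,
    tools,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
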