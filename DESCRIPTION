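Package: woundsizer
Title: Wound Area Measurement from Photographs by Contour-Based
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures the area of a skin wound from a single photograph
    using a deterministic image-processing pipeline: grayscale conversion,
    box blurring, Otsu binarization, contour filtering, morphological
    closing with an elliptical structuring element, Canny edge detection,
    and contour-polygon (shoelace) area summation. Pixel areas are
    converted to square centimetres from the image's physical-resolution
    (DPI) metadata, read from PNG pHYs, JPEG JFIF, or TIFF resolution
    tags. Also provides cross-device calibration by mean absolute
    percentage error with multiplicative adjustment, and a seeded
    synthetic wound-photograph generator with exact ground truth for
    validating the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jpeg,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
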