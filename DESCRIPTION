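Package: sddseg
Title: Cell Segmentation and Quantification by Slope Difference
    Distribution Thresholding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A generalized framework for segmenting and counting cells in
    2-D grayscale microscopy images.  Thresholds are selected from the
    slope difference distribution of the DFT-smoothed intensity histogram;
    intensity and gradient-magnitude segmentations are combined by
    case-specific Boolean unions; threadlike noise blobs are removed by
    morphological opening; blob boundaries are smoothed by periodic
    Fourier low-pass filtering of their contour coordinates; touching
    cells are separated and counted by iterative erosion with area-gated
    seed extraction.  Includes parameter calibration (F-measure grid
    search and a benchmark-free peak-count procedure), synthetic image
    generators with ground truth, and TP/FP/FN scoring of quantification
    results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    png,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
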