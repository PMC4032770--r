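Package: wheatgrade
Title: Wheat Seed Grading from Images by Geometric Features and the Analytic Hierarchy Process
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grades wheat seed kernels photographed on a dark background. Images
    are converted to grayscale, smoothed with a 5x5 Gaussian filter, thresholded
    by Otsu's method and split into 8-connected kernel regions. For each kernel
    five geometric descriptors are extracted: area, Freeman chain-code perimeter,
    circularity, elongation and rectangularity. Seeds are then scored and ranked
    with an analytic hierarchy process (AHP) model: criterion weights are derived
    from a pairwise comparison matrix (with a Saaty consistency test), features
    are normalized by their column maxima, and each seed receives a weighted
    comprehensive coefficient that is thresholded into excellent/good/poor
    grades. Includes a synthetic image and feature-table generator with known
    ground truth, a bundled 14-seed example dataset, and a command-line script.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
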