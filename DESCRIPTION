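Package: immunoseg
Title: Immune-Algorithm Segmentation of Grayscale Brain Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clonal-selection (artificial immune system) optimizers for
    grayscale image segmentation: an immune search over 8-bit threshold codes
    maximizing Otsu between-class variance, and an immune clustering algorithm
    that hybridizes clonal selection with K-means refinement of gray-level
    cluster centers. Includes volume-fraction segmentation metrics (precision
    rate, TPVF, FNVF, FPVF), a synthetic brain-phantom generator with
    pixel-level ground truth, and a benchmark harness comparing the
    thresholding and clustering arms across numbers of divisions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
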