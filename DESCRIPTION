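Package: cyanotrace
Title: Automated Quantification of Filamentous Cyanobacteria in Bright-Field Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, parameterizes, reconnects and measures filamentous
    cyanobacteria (trichomes) in bright-field micrographs of sedimented
    phytoplankton samples. Images are denoised with a Sobel gradient-magnitude
    convolution, segmented into objects, reduced to skeleton graphs, and each
    filament is parameterized as a least-squares spline from which arc length
    and width are measured. Fragments interrupted by debris and branches
    created by crossing filaments are recombined by a cost-based endpoint
    matching step. Includes model-II (Major Axis) regression utilities for
    manual-versus-automated method comparison, a packaged 40-field validation
    dataset from four Italian volcanic lake stations, and a seeded synthetic
    scene generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    splines,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
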