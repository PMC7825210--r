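Package: octavca
Title: Vascular Connectivity Analysis and Morphometry for OCTA Angiograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Segments microvascular networks in en-face optical coherence
    tomography angiography (OCTA) images with a gap-tolerant vascular
    connectivity analysis: starting-point detection by partial line probes,
    region growing with a two-pixel admission distance merged across four
    image rotations, Otsu binarization, Zhang-Suen skeletonization with
    branch-graph noise and artifact filtering, and length/width morphometry.
    Includes a synthetic angiogram generator with exact ground truth,
    longitudinal treatment-monitoring summaries with Welch two-sample tests,
    and ggplot2 visualisation helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jpeg,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
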