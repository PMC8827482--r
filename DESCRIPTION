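Package: wormloop
Title: Closed-Loop Targeted Optogenetic Stimulation of Crawling Worms, Simulated and Analyzed
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A software re-creation of a high-throughput closed-loop targeted
    optogenetic stimulation instrument for populations of crawling
    Caenorhabditis elegans. A synthetic multi-worm arena simulator stands in
    for the camera, projector and plate; on top of it the package implements
    real-time dark-field segmentation and track stitching, a fast two-pass
    recursive centerline algorithm (thinning, branch segmentation,
    longest endpoint-to-endpoint path, 20-point resampling), velocity-based
    behavior-state classification, ellipse-ratio turn-onset triggering with a
    refractory period, head/tail-targeted illumination patterns with
    projector-camera calibration, and the downstream statistics of evoked
    behavior: bootstrapped state fractions, transition-probability surfaces
    with least-squares plane fits and gradients, turn-gated reversal
    probabilities, habituation curves, and throughput and yield accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    grDevices,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
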