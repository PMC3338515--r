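Package: chemofield
Title: Inference and Visualisation of Chemoattractant Fields from Cell Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers the hidden scalar chemoattractant field driving cell
    chemotaxis from observations of cell movement in time-lapse fluorescence
    microscopy. Provides keyhole-model segmentation and tracking of
    fluorescent cells, Kalman-filter/Rauch-Tung-Striebel velocity estimation
    from centroid tracks, Bayesian inference of the field on a multiscale
    squared-exponential basis under the Keller-Segel assumption that cell
    velocity is proportional to the local field gradient, and an agent-based
    chemotaxis simulator supplying ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    png,
    pracma,
    purrr,
    readr,
    rlang,
    scales,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
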