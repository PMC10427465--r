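Package: facefa
Title: Spatially Dense 3D Facial Fluctuating Asymmetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures facial fluctuating asymmetry (FA) from 3D triangulated
    surface scans using a spatially dense geometric-morphometric pipeline: a
    mirror-symmetric template with explicit left-right vertex pairing is
    mapped onto each scan by non-rigid iterative closest points, each mapped
    face is compared with its relabelled mirror image after weighted
    Procrustes superimposition, and the resulting total asymmetry fields are
    decomposed into directional asymmetry (the sample mean) and individual
    fluctuating asymmetry. Also provides landmark-based horizontal, vertical
    and comprehensive FA indices, rating aggregation with interrater
    reliability (two-way average-measures ICC), correlation and standardized
    regression helpers, Fisher-z equivalence tests for correlations against
    stated bounds, a synthetic face-sample and rating generator with known
    asymmetry structure, and a config-driven study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
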