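Package: spherostress
Title: Stored Solid Stress, Stiffness and Morphometry of Tumor Spheroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Physical characterization of multicellular tumor spheroids.
    Implements a plane-strain hyperelastic (Ciarlet-Geymonat) finite-element
    forward model of the opening produced by a partial radial incision in a
    spheroid carrying growth-induced stored stress, and the cdf-sampling
    estimator that infers the Gaussian distribution of stored-stress
    magnitudes from cohorts of incision measurements. Also provides
    Hertz-Sneddon conical-indentation fitting of AFM force curves, voxel-based
    volume and flatness morphometrics, dose-response growth-inhibition
    statistics with Mann-Whitney comparisons, and seeded synthetic-data
    generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    minpack.lm,
    purrr,
    rlang,
    scales,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0), tiff
Config/testthat/edition: 3
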