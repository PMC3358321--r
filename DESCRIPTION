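Package: smlmhough
Title: Hough-Transform Inference of Line and Circle Structures from
    Single-Molecule Localization Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers parametric biological structures (filaments as line
    segments, vesicle-like features as circles) from sparse 2-d
    single-molecule localization microscopy (STORM/PALM) point data using
    classical Hough-transform voting. Provides a synthetic-data simulator
    for ground-truth structure masks with stochastic-activation sampling,
    Gaussian position noise and salt-and-pepper outlier noise; accumulator
    smoothing (2-d median filtering for lines, Laplacian-of-Gaussian plus
    unsharp masking for circles); peak detection with non-maximum
    suppression; complex-wavelet structural-similarity (CW-SSIM) scoring of
    reconstructions against ground truth; density-sweep evaluation with
    replicate statistics of extracted features (filament orientation
    angles, circle diameters); and a multi-scale Laplacian-of-Gaussian
    blob-detection baseline for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    png,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
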