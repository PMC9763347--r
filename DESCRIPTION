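Package: pupilwave
Title: Wavelet Self-Similarity Analysis of Physiological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying self-similarity in noisy physiological
    recordings such as high-frequency pupillometry. Implements an orthogonal
    discrete wavelet transform (Mallat pyramid with periodic boundaries),
    wavelet spectra whose level-wise energies are estimated either by the
    classical sample variance or by the outlier-resistant distance variance
    (with a fast O(n log n) algorithm), Hurst exponent estimation from the
    spectral slope, rolling-window evolutionary slope features with
    Fisher-criterion feature selection, and a classifier evaluation harness
    (logistic regression with Youden-index thresholding, support vector
    machine, k-nearest neighbours). Includes exact fractional Brownian motion
    simulation for validation and a synthetic cohort generator emulating
    multi-session pupil-diameter recordings with blink artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
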