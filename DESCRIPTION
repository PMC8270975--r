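Package: nvcdyn
Title: Neurovascular Coupling Dynamics from Two-Photon Line-Scan Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of neurovascular coupling dynamics from two-photon
    line-scan recordings. Extracts vessel lumen diameter (sub-pixel
    half-maximum boundaries) and red-blood-cell velocity (Radon-style
    streak-angle search) from kymographs, normalizes trial traces
    (delta-F, percent change, baseline z-score), estimates response onset
    latencies by four-parameter sigmoid fitting, estimates gamma-variate
    transfer functions between neuronal calcium and vascular signals by
    simulated annealing with convolution-based cross-prediction, and
    quantifies low-frequency vasomotion bandpower and phase. Includes a
    synthetic-data generator with known ground truth so every stage is
    validated by recovery, and an end-to-end pipeline comparing coupling
    dynamics across brain states.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    signal,
    minpack.lm,
    pracma,
    withr,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
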