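Package: spherelast
Title: Elastography and Brillouin Microscopy Analysis for Tumor Spheroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tumor-spheroid mechanics from two complementary
    optical readouts and analyses longitudinal drug-response studies built on
    them. Implements shear-wave speed inversion from phase-sensitive optical
    coherence elastography depth-time maps (cross-correlation delay
    estimation, slope fitting, Young's modulus via the shear wave equation),
    VIPA Brillouin spectrometer calibration from reference liquids and
    Lorentzian Brillouin-shift extraction, B-scan repeat averaging and
    spheroid segmentation for size tracking, and a nonparametric longitudinal
    statistics layer (exact and approximate Mann-Whitney U, tie-corrected
    Kruskal-Wallis, treated-to-control normalization). A synthetic-data
    module generates every input with known ground truth so the full chain
    is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    broom,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
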