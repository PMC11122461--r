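Package: monktone
Title: Continuous Monk Skin Tone Estimation from Face Images Under Varied Illumination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating continuous skin tone on the 10-point Monk
    Skin Tone Scale from RGB face images captured under heterogeneous light
    sources. Provides the Monk scale colour model with continuous-index
    interpolation and CIELAB conversion, a seeded synthetic studio that
    renders labelled face images under configurable illuminant colour casts
    and intensities, deterministic preprocessing operators (cropping,
    grey-world balancing, pixel shuffling, flip augmentation,
    identity-disjoint splitting, multi-colour-space input tensors), a compact
    convolutional network engine with regression and classification heads,
    transfer-learning style layer freezing and per-light fine-tuning, and an
    evaluation framework built on threshold-accuracy distributions and
    CIELAB error statistics with per-light and per-skin-tone-group
    breakdowns.
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
    readr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    png,
    EBImage,
    withr,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
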