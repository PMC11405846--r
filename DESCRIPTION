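Package: whiskadapt
Title: Sensory and Motor Adaptation Analysis for Active Whisker Touch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sensory adaptation in barrel cortex during
    active whisker-object touch. Computes 3D whisker curvature from quadratic
    Bezier tracking solutions, structures touch sequences within Go/NoGo
    trials, builds per-touch-order spike-count tuning curves with outlier
    filtering and equipopulated binning, predicts unadapted responses by
    cross-validated tuning-curve evaluation, and quantifies adaptation with
    the alpha attenuation-decomposition index and the whisker-specific
    adaptation index I. Includes a seeded synthetic-session generator with
    ground-truth adaptation schedules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
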