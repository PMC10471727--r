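Package: forelandclim
Title: Soil Microclimate Reconstruction and Buffering in Glacier Forelands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs monthly near-subsurface soil temperature in glacier
    forelands from downscaled macroclimate, topographic shortwave radiation,
    snow-free-day frequency and proglacial covariates, using a linear mixed
    model with a per-glacier random intercept. Includes terrain derivatives
    and lapse-rate downscaling, hourly topographic solar radiation with
    clearness-index direct/diffuse separation, snow-cover detection from
    logger diurnal ranges and fractional snow cover with threshold
    calibration, a hierarchical observation-weighting scheme with weighted
    agreement statistics, leave-one-glacier-out transferability analysis,
    and projection utilities for microclimate change and buffering potential
    between two periods. A fully synthetic proglacial world generator with
    stored ground truth makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
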