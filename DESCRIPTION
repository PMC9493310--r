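Package: phenoforce
Title: Climate Extreme Indices and Phenology Forcing for Crop Phenophase Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes percentile-screened climate extreme indices (CEI) for six
    sub-categories of extreme environmental events (high/low temperature,
    high/low precipitation, drought duration, wind) from daily weather series,
    and derives crop phenology impact metrics from phenophase shift tables:
    the phenology shift index, phenology sensitivity, and the phenology
    forcing index with a minimum impact limit. Includes seeded synthetic
    weather and phenophase-shift generators with known ground truth,
    Monte-Carlo sensitivity and uncertainty analyses of the forcing model,
    and inverse-variance meta-analytic summaries (forest/funnel) for
    verification, plus a small command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    metafor
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
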