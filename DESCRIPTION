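Package: vaximpact
Title: Estimating the Coverage Impact of New Vaccine Technologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the effect of new vaccine technologies (for example
    micro-array patches or thermostable presentations) on vaccination coverage
    rates in low- and middle-income country immunization programs. Models each
    individual as facing a set of technology-addressable barriers to
    vaccination, combines per-barrier population prevalences with per-barrier
    vaccine technology scores under an independence assumption, and anchors the
    resulting uncalibrated coverage to observed coverage of an already-deployed
    calibration vaccine through a linear calibration. Includes a five-level
    scoring rubric for vaccine presentation characteristics, priority-fallback
    resolution of proxy indicators into population barrier scores, blending of
    routine and campaign vaccination channels, population-weighted
    multi-country aggregation with an extreme-value exclusion rule, a
    subnational coverage-equity index, scenario configuration with sensitivity
    sweeps, and a synthetic-data generator with an agent-level Monte-Carlo
    check of the analytic model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
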