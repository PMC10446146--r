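Package: nanorelease
Title: Nanoparticle Release Quantification and Indoor Exposure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies engineered-nanomaterial release from photocatalytic
    air-purifier surfaces and predicts the resulting indoor exposure. Provides
    a well-mixed single-compartment aerosol mass-balance model with closed-form
    and numerical solutions, emission-rate inference from chamber concentration
    time series via windowed time derivatives, conversion of filter-based
    titanium gravimetry (including results censored at the limit of
    quantification) into release factors in generalized units, and
    deterministic multi-purifier room-exposure scenarios compared against
    proposed occupational exposure limits for nanosized TiO2. Includes a fully
    seeded synthetic-data generator so every pipeline stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
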