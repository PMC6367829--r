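Package: interplay4d
Title: 4D Dose Accumulation and Interplay-Effect Simulation for Scanned
    Proton Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for the interplay effect in pencil-beam
    scanning (PBS) proton therapy of abdominal (pancreatic) targets under
    periodic breathing motion. Generates a synthetic patient phantom with
    target and organ-at-risk structures, periodic 20-phase deformation
    vector fields with patient-like amplitudes, and synthetic 4D CTs by
    image warping. Provides deformation-field quality assurance (Jacobian
    determinant maps, mass-conservation ratios), a simplified analytic
    pencil-beam-scanning proton dose engine with single-field uniform dose
    planning and a delivery time structure, time-resolved 4D dose
    accumulation over breathing phases, stochastic fractionation simulation
    with random per-fraction motion patterns and starting phases,
    dose-volume-histogram metrics (d5/d95, v95, v107, d2, dmean, v30) with
    rank-sum comparisons, and weighted-correlation significance statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    RNifti,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
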