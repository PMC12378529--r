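Package: glycotrack
Title: Glycation Metrics from Circulating Biomarkers for Cardiovascular Tissue Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes proxy metrics of in-situ cardiovascular tissue glycation
    from four routine blood biomarkers (hemoglobin A1c, fructosamine,
    high-sensitivity cardiac troponin I and direct LDL). A two-point
    slope-intercept extrapolation across substrate half-lives yields troponin
    and LDL glycation rates (TGR, LGR) and indices (TGI, LGI); supporting
    tooling covers NGSP/IFCC unit conversion, quartile banding and
    exclusionary-limit screening, sequential annual tracking with
    next-year ordinary-least-squares forecasting, multi-decade trajectory
    simulation with cumulative excess-burden AUC, a seeded synthetic-cohort
    generator, and a command-line interface over CSV laboratory panels.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
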