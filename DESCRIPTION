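Package: vspkit
Title: Quantitative Analysis of Voltage-Sensing Phosphatase Domain Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative characterisation of voltage-sensing
    phosphatase (VSP) domain-membrane coupling. Classifies membrane binding of
    the phosphatase and C2 domains and the productive orientation of the
    cytoplasmic catalytic region frame-by-frame in molecular dynamics
    trajectories; estimates voltage-dependent phosphatase activity as the
    exponential decay rate of normalized Kir test-pulse currents over
    accumulated depolarization time; integrates off-sensing gating charge with
    P/N leak subtraction; and decomposes voltage-clamp fluorometry F-V curves
    into one or two Boltzmann components with model selection and kinetic
    analysis. A synthetic-data module generates every input with recorded
    ground truth so the whole pipeline is testable without experimental data.
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
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
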