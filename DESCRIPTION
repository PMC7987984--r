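Package: fertcurve
Title: Parametric Models for Single-Year Age-Specific Fertility Schedules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and compares nine parametric models of the single-year
    age-specific fertility rate (ASFR) over ages 15-49: the Hadwiger curve,
    the Peristera-Kostaki double-Gaussian, the Gompertz fertility curve, the
    Azzalini skew normal, the Gupta-Pasupuleti beta-kernel curve, and
    modified forms of the latter four that add a late-age constant, a scale
    exponent, split spreads, or a shifted support. Provides bounded
    multi-start nonlinear least squares via nlminb, small-sample corrected
    AIC (AICc) model selection, tricube local-polynomial (loess) smoothing,
    estimation of single-year ASFR from retrospective birth-history
    microdata in DHS century-month coding, seeded generators for synthetic
    schedules and birth histories, and reference parameter estimates for the
    2015-16 Indian National Family Health Survey (NFHS-4) schedules of India
    and six states.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
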