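Package: climwindow
Title: Climate-Window Selection and Overdispersed Count Models for
    Waterbird Population Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating long-term monthly waterbird counts to
    climate variability in Mediterranean wetlands. Enumerates candidate
    climate time-windows (all durations and one-month-shifted positions
    over the focal and previous year), selects the window and climatic
    variable best rank-correlated with seasonal abundance, and fits
    quasi-Poisson generalized linear models of counts against the
    selected climate signal and vegetation cover, with overdispersion
    and collinearity diagnostics. Includes an NDVI-threshold vegetation
    cover stage and a seeded synthetic-data generator that emulates the
    study design (18 years x 12 months x 4 species) with known ground
    truth, so the whole pipeline is testable end to end.
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
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    withr,
    yaml,
    zoo
Suggests:
    broom,
    car,
    jsonlite,
    lmtest,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
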