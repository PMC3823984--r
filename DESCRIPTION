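Package: probistab
Title: Accelerated Stability Modelling of Probiotic Powders by First-Order
    Kinetics and the Arrhenius Equation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mechanistic shelf-life prediction of dried probiotic
    products from plate-count stability studies. Fits first-order viability-loss
    kinetics ln(Nt/N0) = -k*t per storage temperature, derives decimal-reduction
    times (D1, D2, D3), models the destruction rate k across temperatures with
    the Arrhenius equation k = A*exp(-Ea/(R*T)), extrapolates k to accelerated
    conditions, predicts viable counts at any temperature and time, solves for
    shelf-life against a specification limit, and evaluates new batches against
    a reference kinetic with a relative tolerance band and a through-origin
    guiding coefficient. Includes a reproducible synthetic plate-count generator
    (lognormal between-replicate variability plus Poisson counting noise on ICH
    Q1A checkpoint schedules) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
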