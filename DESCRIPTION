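Package: mvpatiming
Title: Discrete-Time Survival Analysis of Daily Physical Activity Timing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for locating the time of day when adolescents accumulate
    their person-specific average moderate-to-vigorous physical activity
    (MVPA) from wrist accelerometer data. Implements epoch-level
    preprocessing (nonwear detection from consecutive zero-count runs,
    actigraphic sleep scoring, count-cutpoint intensity classification,
    valid-day inclusion rules), construction of a discrete-time
    person-period risk set whose event is first attainment of the personal
    daily MVPA average, multilevel logistic hazard models with polynomial
    time and moderator interactions fitted by adaptive Gauss-Hermite
    quadrature, odds-ratio / hazard / survival effect tables, and
    empirically derived intervention decision points for just-in-time
    adaptive interventions. Includes a synthetic cohort generator so the
    whole pipeline is testable without access to raw cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    Matrix,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
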