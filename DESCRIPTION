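Package: stagesen
Title: Multistage-Senescence Modelling of Age-Specific Cancer Incidence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits the multistage-senescence model of carcinogenesis to
    registry-style age-specific cancer incidence rates. Provides the
    closed-form model equations (Armitage-Doll power law with a linear
    senescence tumor-suppression term), weighted nonlinear least-squares
    fitting of per-cancer stage number, stage-transition rate and
    senescence parameters, derived statistics (age and rate of peak
    incidence, lifetime cumulative probability), cross-cancer comparative
    statistics, a driver-gene stage decomposition, and a synthetic
    Poisson-registry generator for parameter-recovery validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
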