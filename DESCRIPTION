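Package: posdev
Title: Positive Deviance Analysis for Multi-Objective Household Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies "positive deviant" farming households from
    RHoMIS-style multi-indicator survey tables. Computes five household
    performance indicators (caloric food security, dietary diversity, cash
    income, greenhouse-gas score, gender equity), converts them to relative
    performance via median-regression residuals with AIC covariate
    selection, finds Pareto-optimal households in the five-dimensional
    residual space, profiles deviance across land-by-livestock resource
    strata, selects a maximally diverse case subset by mean crowding
    distance, and matches every household to its nearest positive-deviant
    "resource homologues" to derive household-specific practice menus.
    Includes a seeded synthetic-survey generator with planted deviants for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    quantreg,
    yaml,
    jsonlite
Suggests:
    readxl,
    optparse,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
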