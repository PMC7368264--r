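Package: momage
Title: Age-by-Maternal-Age Matrix Population Models of Maternal Effect
    Senescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits maternal-age-dependent survival (Weibull) and fertility
    (Coale-Trussell) models to individual daily life tables with right
    censoring, assembles the age-by-maternal-age block projection matrix,
    and computes fitness (the dominant eigenvalue), stable structure,
    reproductive values, net reproductive rate, selection gradients on every
    age- and maternal-age-specific vital rate, stationary-population scenario
    variants, and life table response experiment (LTRE) decompositions of the
    fitness cost of maternal effect senescence. Includes an individual-based
    cohort simulator emulating daily life-table experiments so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
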