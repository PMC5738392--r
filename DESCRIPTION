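Package: genloewe
Title: Generalized Loewe Null Models and Synergy Testing for Checkerboard
    Combination Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the expected effect of drug combinations under a
    biochemically interpretable generalization of Loewe concentration
    additivity that accommodates partial, neutral and inverse agonists
    with unequal maximal responses. Mono-therapy curves are fitted by
    shared-baseline four-parameter log-logistic non-linear least squares;
    the occupancy-weighted null response surface is computed for every
    off-axis dose combination; and synergy or antagonism is called with
    the MeanR and MaxR lack-of-fit tests using parametric or bootstrap
    null distributions. Includes a checkerboard simulator for type-I
    error and power studies and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
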