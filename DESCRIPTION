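Package: ebprob
Title: Logistic Regression Surrogates for Cardiac Ectopic-Beat Probability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds logistic-regression surrogate models that map myocyte
    model inputs (initial cytosolic and sarcoplasmic-reticulum calcium,
    inward-rectifier potassium conductance and ryanodine-receptor opening-rate
    scaling factors) to the probability of delayed-afterdepolarization-induced
    ectopic beats. Implements a two-iteration adaptive sampling design with
    transition-domain refinement and exhaustive quadratic-feature selection by
    consistent AIC, Monte Carlo and analytic (logit-normal) propagation of
    input uncertainty to the event-probability distribution with entropy and
    modality summaries, model-characteristic curves and domain classification,
    a seedable stochastic event simulator with a known probability surface for
    end-to-end validation, and reconstruction of a published ectopic-beat
    model from its printed weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
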