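Package: glucoge
Title: Hybrid Blood-Glucose Forecasting by Grammatical Evolution with
    Physiological Preprocessing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mid-term (120-minute) blood-glucose forecasting for type 1
    diabetes from continuous glucose monitoring (CGM), carbohydrate and
    insulin records.  Discrete meal and insulin events are transformed into
    continuous rate-of-appearance and insulin-on-board signals by
    two-compartment physiological models, and a grammatical-evolution
    symbolic-regression engine evolves personalized piecewise predictors
    (one per day segment) under a glucose-specific penalized fitness.
    Includes clinically weighted accuracy metrics, Clarke error-grid
    analysis, and a synthetic virtual-patient cohort generator for
    end-to-end experimentation without access to a proprietary simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
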