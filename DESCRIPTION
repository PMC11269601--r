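Package: apexri
Title: Power-Exponential Practice Curves with Reactive Inhibition for
    Motor Sequence Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative modelling of trial-structured motor sequence
    response times to decide whether skill learning is online (during
    practice), offline (during breaks between trials), or a hybrid of
    both.  Implements eight model variants that combine a
    power-exponential (APEX) skill function with additive
    reactive-inhibition terms, fits them to participant-averaged
    sequence response times by bounded nonlinear least squares with
    grid-search initialisation, compares them by BIC, and converts the
    fitted break-learning parameter into an offline-learning
    proportion.  Includes preprocessing of raw keypress logs (sequence
    scoring, geometric-mean response times, warm-up removal, error
    summaries), a synthetic keypress-data generator with known ground
    truth, and parameter- and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
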