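Package: exermet
Title: Personalized Exercise Layer for Whole-Body Fuel Homeostasis Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the hormonal response to a session of sub-maximal
    aerobic exercise. Converts between work rate, oxygen cost and relative
    exercise intensity (%VO2max) for five exercise modalities, models
    suprabasal oxygen-uptake kinetics with a first-order step response,
    drives an epinephrine secretion/elimination model from oxygen uptake and
    arterial glucose, and couples epinephrine into a proportional
    insulin/glucagon controller. Includes weighted nonlinear least-squares
    estimation (Levenberg-Marquardt) of the epinephrine-to-insulin coupling
    with Fisher-information precision, encoded validation-study protocols,
    a synthetic-observation generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
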