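Package: fairdx
Title: Fairness Auditing, Bias Mitigation and Compartmental Epidemic
    Modelling for Cardiovascular Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to audit and mitigate group bias in binary clinical risk
    models, built around a reproducible synthetic-cohort generator for the
    standard cardiovascular tabular schema (age, anthropometrics, blood
    pressure, cholesterol, glucose, lifestyle factors, binary outcome).
    Implements the group-fairness metric suite (difference in mean outcomes,
    demographic parity, disparate impact, equal opportunity difference,
    average odds difference, Theil index, balanced accuracy), post-processing
    mitigation operators (reweighting, balanced probability adjustment,
    equalised-odds score scaling, exhaustive counterfactual search),
    SIR/SCIR compartmental ordinary-differential-equation models with
    bias-adjusted transmission and sensitivity sweeps, and segmentation and
    annotation agreement statistics (Dice, intersection-over-union, Cohen's
    kappa) for mask and bounding-box data. All analyses are driven by plain
    data frames and return tibbles so results compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
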