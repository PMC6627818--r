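Package: thermoresp
Title: Intermittent-Flow Respirometry Simulation and Metabolic Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates intermittent-flow respirometry trials (flush/wait/measure
    cycles with thermal ramps, handling-stress decay and spontaneous activity),
    extracts oxygen consumption rates (MO2) from PO2 traces by per-cycle linear
    regression with r-squared quality control, standardizes rates to a common
    body mass by allometric scaling, estimates standard metabolic rate (SMR) as
    the mean of the lowest component of a fitted normal mixture, derives maximum
    metabolic rate (MMR), absolute and factorial aerobic scope and Q10 thermal
    sensitivity, and compares populations with pooled t-tests and a
    random-intercept linear mixed model with likelihood-ratio tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    nlme
Config/testthat/edition: 3
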