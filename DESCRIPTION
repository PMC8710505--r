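Package: htncea
Title: Markov Cohort Cost-Utility Analysis of Hypertension Management Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cost-utility analysis of community hypertension-management
    programmes with a nine-state Markov cohort model (prehypertension, three
    hypertension grades, myocardial infarction, stroke, congestive heart
    failure, end-stage renal disease, and death). Estimates annual transition
    probabilities, blood-pressure control rates, and SF-36-mapped EQ-5D
    utilities from longitudinal follow-up records; runs lifetime cohort
    simulations with age-dependent background mortality and discounting;
    computes incremental cost-effectiveness ratios, net monetary and net
    health benefits; and quantifies uncertainty by one-way (tornado) and
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves. Includes a synthetic-trial generator with known ground truth so
    the whole estimation-to-decision pipeline can be tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
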