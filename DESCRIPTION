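Package: physupply
Title: Markov State-Transition Projection of the UK Consultant Physician
    Workforce
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time Markov cohort model of the UK physician
    training pipeline, from medical school entry to consultant working,
    retirement and exit.  Estimates annual transition probabilities from
    longitudinal person-year training records (with a three-year rule to
    separate temporary breaks from exits), projects whole-time-equivalent
    (WTE) consultant supply over a 25-year horizon with external inflows,
    compares supply against compounding demand scenarios, and implements
    composable policy scenarios (medical-school intake ramp, reduced
    training exit, overseas inflow scaling, less-than-full-time drift).
    Includes an agent-level microsimulation cross-check of the
    deterministic engine and a synthetic-data generator with known
    ground-truth probabilities for estimator validation, standing in for
    restricted registry sources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
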