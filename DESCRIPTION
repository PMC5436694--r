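Package: dialysisCEA
Title: Cost-Effectiveness and Budget Impact of Dialysis Policy Options in
    End-Stage Renal Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov cohort state-transition model for the economic evaluation
    of renal replacement therapy policies (peritoneal-dialysis-first,
    hemodialysis-first, and conservative supportive care) in end-stage renal
    disease under the Indonesian universal health coverage setting.
    Implements the deterministic cohort engine with annual treatment cycles
    and monthly complication sub-states, lifetime cost and QALY accrual under
    societal and healthcare-provider perspectives, incremental
    cost-effectiveness and dominance analysis, probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, a five-year budget
    impact projection, a patient-level microsimulation oracle, and a
    synthetic questionnaire-data generator for the cost and utility inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
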