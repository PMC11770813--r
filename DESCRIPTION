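Package: dgtt
Title: Deuterated-Glucose Glucose and Insulin Tolerance Test Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for intraperitoneal glucose and insulin
    tolerance tests performed with [6,6-2H2]glucose tracer in rodents.
    Converts LC-MS/MS glucose isotopologue peak areas into molar tracer
    enrichment (natural-abundance and tracer-purity correction by
    non-negative least squares), partitions total blood glucose into
    exogenous (tracer-derived) and endogenous components, summarises
    curves as baseline-subtracted signed trapezoidal areas (AOC), and
    tests diet-by-insulin factorial effects with per-timepoint group
    comparisons. Includes a glucose-insulin kinetics simulator that
    generates synthetic cohorts with a full measurement model so every
    pipeline stage can be validated against ground truth, and a
    lean-mass-normalised dose planner for both test modes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
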