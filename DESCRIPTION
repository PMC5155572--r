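Package: fscombo
Title: Feedback-Driven Optimization of Multi-Drug Dose Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-loop ("feedback system control") optimization of
    combination chemotherapy regimens over a discrete drug-dose grid.
    Implements differential evolution on integer dose-level space driven
    by a pluggable cell-viability oracle, the average cumulative survival
    (ACS) objective with effective/not-effective classification,
    therapeutic-window selectivity metrics, chemoresistance profiling from
    dose-response IC50 estimates, second-order response-surface regression
    with hierarchy-aware stepwise simplification and drug-interaction
    interpretation, and digitization/correlation analysis of dual-luciferase
    pathway-reporter readouts. A Hill-type multi-cell-line viability
    simulator with Bliss-deviation pairwise interactions stands in for
    plate assays so the whole loop runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
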