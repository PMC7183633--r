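Package: emaflow
Title: Deterministic Engine and Simulator for mHealth Study Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A headless engine for JSON-defined mobile-health study
    protocols: a validating parser for a canonical protocol dialect,
    a notification scheduler with random jitter, timeouts and a rolling
    capped pending set, multi-level randomisation (condition allocation,
    section and question shuffling, element-group selection), survey
    branching logic, a participant session runtime with offline response
    queueing, and a synthetic-participant simulator that drives complete
    study designs (cross-sectional, ecological momentary assessment,
    randomised controlled, just-in-time adaptive and micro-randomised
    trials) and exports analysis-ready response tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
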