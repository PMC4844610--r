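Package: feedcircuit
Title: Simulation and State-Space Analysis of the Hypothalamic Food-Intake
    Control Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A calibrated simulator and state-space analysis engine for a
    feedforward network model of the hypothalamic control of food intake.
    Twelve neural units (eight hypothalamic, four brainstem/midbrain output
    units) transform the levels of five feeding-related substances (leptin,
    ghrelin, CCK, serotonin, glucose) into a level of food intake. Receptor
    strengths and unit biases (51 parameters) are calibrated with a genetic
    algorithm against a truth table of 32 published experimental
    manipulations using a 30 percent change criterion. The nondeterministic
    update semantics (hypothalamic units may update; output-stage units must)
    induces a state-transition tree that the package enumerates exhaustively
    with deduplication, supporting predicate search over response
    configurations, "whenever p then q" invariant checking with
    counterexample witnesses, percent-activity normalization and food-intake
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
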