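Package: stopbci
Title: Closed-Loop Volitional Stop-Signal BCI Simulation and Photometry Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a closed-loop volitional stop-signal (GO/NO-GO)
    brain-computer interface paradigm in which a synthetic mouse agent
    controls a population calcium signal against a threshold, and analyses
    the resulting fiber-photometry traces and behavioral event logs.
    Provides a parametric generator for multi-region calcium traces with
    event-locked GCaMP-like transients, a trial/session state machine with
    withdrawal and random-reward variants, chemogenetic and optogenetic
    effect models, moving-average smoothing, dF/F conversion, peri-event
    alignment, component peak extraction, and two-group nonparametric and
    parametric statistics with per-mouse session averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
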