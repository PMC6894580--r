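Package: motib
Title: Simulation and Analysis of Sustained Inattentional Blindness in
    Multiple Object Tracking Displays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded simulator of the multiple-object-tracking bounce-counting
    display used in sustained inattentional blindness experiments, together
    with generative observer models of noticing (onset-window, offset-window,
    fixation-crossing and constant-hazard accounts), the standard exclusion
    pipeline including Farnsworth D-15 confusion-index scoring, percentile
    bootstrap and circular-error analyses of noticing rates and feature
    reports, and a model-discrimination stage with parameter recovery.
    Synthetic cohorts make the whole inferential pipeline testable without
    human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
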