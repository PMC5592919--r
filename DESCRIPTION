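Package: wormsleep
Title: Quantification of Developmentally Timed Sleep in C. elegans and
    Screen Triage Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Velocity-based sleep-bout segmentation and pooled population
    sleep metrics (fractional population sleep, bout frequency, mean sleep
    bout duration) for multi-worm tracker recordings of C. elegans L4-to-adult
    lethargus; an image-subtraction quiescence pipeline for single-animal
    chamber recordings with rolling fractional quiescence and rule-based
    lethargus boundary detection; retention rules and retrospective statistics
    for a three-stage forward-genetic sleep screen (plate-level retention,
    population sleep selection, per-animal t-tests, Fisher's exact test,
    saturation estimates); and simulators for alternating sleep/motion bout
    processes, velocity traces, rendered chamber image stacks and plate
    scores, so every stage of the analysis is testable on synthetic data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
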