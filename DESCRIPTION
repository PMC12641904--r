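Package: pupilrecover
Title: Dark-Adaptation Recovery Analysis of the Pupillary Light Reflex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying recovery of the pupillary light reflex (PLR)
    after light adaptation with an incrementing bright/dark stimulation
    protocol. Builds the stimulation schedule, simulates 200 Hz pupil-diameter
    recordings under a saturating-exponential dark-adaptation recovery law
    (with hippus, measurement noise and blink dropouts), cleans traces,
    extracts cycle-wise constriction amplitudes from fixed regions of
    interest after light re-onset, fits linear mixed-effects models of
    amplitude on dark duration, group and age, and classifies subjects from
    their 50-point recovery curves with a small one-dimensional convolutional
    network under stratified five-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
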