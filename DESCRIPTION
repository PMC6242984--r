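Package: facegaze
Title: Gaze Analysis of Dynamic Facial-Expression Viewing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analyzing eye-tracking data recorded while
    observers categorize dynamic facial expressions of emotion. Segments
    500-Hz gaze sample streams into fixations, saccades and blinks with a
    velocity-threshold (I-VT) algorithm, attributes fixations to facial
    regions of interest (eyes, nose/cheek, mouth), computes per-trial and
    by-items attention metrics (probability of first fixation, probability
    and time of entry, net gaze duration, number of fixations), bins net
    gaze into 100-ms intervals to locate the threshold and amplitude of
    each expression's attentional advantage, tabulates categorization hits,
    reaction times and confusions, and reports by-items ANOVAs with partial
    eta squared, single-step Bonferroni contrasts and compact letter
    displays. Includes a seeded synthetic scanpath and response generator
    so the full pipeline is testable without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
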