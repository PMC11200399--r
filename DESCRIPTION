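Package: ethotrack
Title: Time Budgets and False-Positive Filtering for Detector-Based
    Behavioral Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-detection analysis of per-frame bounding-box detector
    output from CCTV monitoring of captive animals. Builds ethogram time
    budgets from detector output and from manual codings and compares
    them, filters false-positive Locomotion frames by detecting plateaus
    in the label-box bottom-corner coordinates, classifies gross postures
    from the box height/width ratio, and ships a synthetic
    detection-stream generator (behavior bouts, box trajectories,
    detector noise) so the whole pipeline is testable without video or a
    trained model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    xml2,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
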