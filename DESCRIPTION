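Package: reachbci
Title: Simulation Toolkit for an EEG-Triggered Assistive Reach System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computational core of a brain-computer-interface driven assistive
    reach device: forward/inverse kinematics of a 3-DoF serial arm from
    Denavit-Hartenberg parameters, a gradient-descent reach planner with
    quantized servo readout and positional-error accounting, planar
    pixel-to-world mapping from fiducial-marker correspondences, an EEG
    frequency-band-power trigger classifier stack (single-feature threshold
    sweeps, adaptive boosting over decision trees, a small feed-forward
    network, five-fold cross-validation, stream decoding with debounce),
    seeded synthetic-data generators for band-power streams, tabletop scenes
    and prompting sessions, and an end-to-end trial simulator with confusion
    tallying, latency ledgers and usability scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
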