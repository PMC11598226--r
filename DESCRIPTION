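Package: somnoposture
Title: Contactless Sleep-Posture Monitoring with Ultrasonic Sensor Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates an overhead array of six ultrasonic time-of-flight
    sensors plus a passive-infrared occupancy gate watching a subject on a
    bed, fuses the echo distances into 6-bit posture presence words, and
    classifies the words with a hierarchical binary decision tree over the
    leg, abdomen and head sensor pairs. Includes FIFO-based posture
    learning into bounded subject profiles with adaptive slots for
    non-standard postures, a debounced streaming evaluator that emits
    confirmed posture segments and transition durations, accuracy and
    pipeline-latency metrics, and an end-to-end pipeline with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
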