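Package: dldflow
Title: Automated Particle Counting and Separation-Mode Classification
    for Deterministic Lateral Displacement Devices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis automation for high-throughput deterministic lateral
    displacement (DLD) microfluidic separation experiments. Reads grayscale
    high-speed-camera image sequences of the outlet-channel region,
    automatically de-skews frames, locates the observation window by template
    matching and line detection, segments the outlet-channel walls, and counts
    particles by background subtraction and consecutive-frame differencing
    with a repeat-detection rule set that prevents double counting. Per-outlet
    particle distributions, together with flow rate and particle size, feed
    three comparable classifiers (complement naive Bayes, k-nearest
    neighbors, and a radial-basis-function support vector machine) that
    predict the DLD separation mode (zigzag, mixed, or bumped) under
    stratified k-fold cross-validation. A seeded synthetic-fixture generator
    renders ground-truthed outlet videos and mode-labeled datasets so the
    whole pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    class,
    e1071,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
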