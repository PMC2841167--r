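Package: gazemap
Title: Fixation-Map Statistics for Gaze-Contingent Face-Recognition Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing eye-movement data from gaze-contingent
    ("Spotlight") face-recognition experiments: saccade/fixation/blink event
    parsing with velocity and acceleration thresholds, Gaussian-aperture mask
    rendering and landmark visibility, duration-weighted fixation maps with
    Gaussian smoothing and pooled Z-scoring, random-field (Euler
    characteristic) critical thresholds for smooth Z-maps ("Pixel test") with
    signed cluster extraction, region-of-interest effect sizes via two-way
    mixed ANOVA and Cohen's d, percentile-bootstrap time-course inference,
    pixel-space image diagnosticity statistics, and a fully seeded synthetic
    generator of face-like stimuli, observer fixation strategies and
    1000 Hz gaze traces so every stage is testable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    data.table,
    jsonlite,
    yaml,
    png,
    igraph,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
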