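Package: oculog
Title: Auto-Calibrating Saccade and Blink Detection from Electro-Oculography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic analysis of two-channel electro-oculographic (EOG)
    recordings without any user calibration. Amplitude thresholds for
    horizontal saccades, vertical saccades and blinks are estimated from the
    recording itself by a pivot-point (knee) search on the sorted curve of
    scaled signal peaks; events are extracted as bounded peaks in the velocity
    and positional signals, classified into five classes (horizontal,
    vertical and oblique saccades, blinks, and saccades coinciding with
    blinks), and reported with temporal and kinematic measures (duration,
    peak velocity, acceleration, eye closing and opening times). Includes
    polynomial baseline-drift removal and Haar wavelet band truncation,
    readers and writers for delimited-text and EDF signals, a ground-truth
    synthetic EOG generator for benchmarking, event-matching evaluation
    (sensitivity, false-positive rate, confusion matrices), and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
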