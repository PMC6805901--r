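Package: myobeat
Title: Contraction Quantification from Transmitted-Light Video by Frame Differencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies the contractility of beating cells and whole hearts
    from ordinary transmitted-light video. Two per-frame signals are
    extracted by absolute frame differencing: "speed" (mean absolute
    pixel change between consecutive frames) and "amplitude" (mean
    absolute pixel change against a resting-phase reference frame).
    Contracting regions are segmented automatically from an accumulated
    activity map, beats are detected with a sensitivity parameter, and
    every beat is decomposed into systolic, diastolic and overall peak
    times at four dynamically recomputed thresholds. Includes a
    synthetic-video generator for validation, tab-separated result
    files supporting full re-analysis without the video, and a batch
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
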