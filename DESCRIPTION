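Package: larvasleep
Title: Video-Based Quantification of Larval Sleep, Arousal, Feeding, Memory,
    and Calcium Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-well time-lapse recordings of
    Drosophila larvae. Converts grayscale image stacks into per-well activity
    traces by temporally adjacent frame differencing with a binary gray-scale
    threshold, calls sleep as zero-activity inter-frame intervals, decomposes
    sleep into bouts and circadian-window summaries, and scores arousal from
    stimulus-locked activity changes. Also computes mouth-hook feeding rates,
    dye-based food intake, naive odor preferences, reciprocal two-odor
    conditioning preference scores and the associative performance index, and
    baseline-normalized calcium (delta F over F) trace statistics. A
    synthetic-data generator produces every pipeline input with known ground
    truth (two-state behavioral Markov chains rendered as moving blobs in
    wells, stimulus-evoked responses, multinomial choice counts, and calcium
    transients) so the full pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
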