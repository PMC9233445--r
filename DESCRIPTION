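Package: sleepreplay
Title: Detection of Sleep Replay of Practiced Motor Sequences in Intracortical Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for detecting offline replay of a
    practiced motor sequence in intracortical motor-cortex recordings.
    Provides steady-state Kalman filter calibration and offline decoding of
    binned neural features into hypothetical 2-D cursor trajectories,
    trajectory-template matching with simultaneous threshold crossing events
    (STCEs), Youden's J threshold optimization, a channel firing-order
    matching index with a random-sequence control, pseudo-template and
    phase-randomized bootstrap nulls, a temporal-compression sweep, EEG-based
    sleep staging via the 95 percent frequency power limit, and cortical
    ripple detection with STCE-ripple alignment. A synthetic-session
    generator with ground-truth injected replay makes every stage verifiable
    in the absence of participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
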