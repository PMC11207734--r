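Package: mmsync
Title: Multimodal Synchronization Toolkit for Lab-Streamed Neurophysiological Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating and repairing the temporal alignment of
    independently clocked physiological data streams recorded around an
    instrumented treadmill with projection-based visual stimulation: a
    photodiode byte-trigger codec with Schmitt-trigger digitization, affine
    clock alignment with jitter diagnostics for the display chain,
    center-of-pressure movement-onset detection from force-plate data, and
    stimulus- or onset-locked event-related pipelines for visually evoked
    potentials (N75/P100), rectified EMG averages, and fNIRS hemodynamic
    responses via the modified Beer-Lambert law with short-channel
    regression.  A built-in acquisition simulator generates complete
    synthetic sessions (checkerboard reversal and start-to-go stepping
    tasks) with ground-truth display times, movement onsets, and clock
    parameters, in both a correct single-script and a faulty two-script
    display-trigger mode.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    zoo,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
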