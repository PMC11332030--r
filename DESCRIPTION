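Package: plvsync
Title: Auditory-Motor Synchronization Analysis with Phase-Locking Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing auditory-motor synchronization experiments in
    which participants tap or whisper along with accelerating syllable or tone
    sequences. Provides stimulus onset scheduling (accelerating synchronization
    sequences and isochronous deviant-detection sequences), cochlear-style
    amplitude-envelope extraction from audio, windowed phase-locking values
    with a segment-shuffling permutation baseline, envelope spectral-peak
    features, participant quality-control screens, principal-component
    analysis with varimax rotation and the Kaiser-Guttman criterion, JZS
    Bayes factors for paired t-tests with Monte-Carlo design analysis, and a
    synthetic-data generator with known ground truth (error-correcting
    oscillator model, latent-component participant populations, psychometric
    deviant-detection responses) for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
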