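Package: gastroEGG
Title: Electrogastrogram Band-Power Analysis and Gastric Biofeedback Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cutaneous electrogastrography (EGG): a seeded synthetic
    EGG generator emulating a 1000 Hz, 16-bit single-channel abdominal
    recording; the offline spectral pipeline used in gastric biofeedback
    research (cascaded anti-aliased downsampling to 10 Hz, linear detrending,
    zero-phase Butterworth bandpass over 0.016-0.16 Hz, Hann-windowed
    zero-padded FFT, and percent power in the bradygastric, normogastric and
    tachygastric bands); a causal real-time feedback engine mapping a live
    sample stream to pacemaker, direct-feedback and spectral
    ("dimensional FFT") feedback states; session-level summaries over
    baseline/training/post recordings with group winsorization; and readers
    and writers for plain delimited and OpenSignals-style text recordings,
    with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
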