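Package: tipscoder
Title: Cochlear-Implant Pulse-Pattern Coding and Temporal-Masking Sparsification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating cochlear-implant sound coding and the
    temporal integrator processing strategy (TIPS), a post-processor that
    removes stimulation pulses predicted to be perceptually masked. Implements
    an acoustic front end (RMS calibration, pre-emphasis, FFT filterbank
    envelope extraction, loudness-growth compression), CIS and ACE (N-of-M)
    pulse-pattern encoders with stimulation-cycle timing feasibility, the
    temporal-integrator masking window and per-pulse decision device with
    criterion calibration to target removal fractions, a clinical-current-unit
    power-savings model, synthetic stimulus generators (tones, speech-shaped
    noise, multi-talker babble proxy, speech-like tokens), and a simulator of
    the adaptive speech-reception-threshold measurement procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
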