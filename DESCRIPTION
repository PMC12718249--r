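Package: dyadsync
Title: Dyadic Neurophysiological Synchrony: RSA Coupling, fNIRS Wavelet
    Coherence, and Moderation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of mother-child neurophysiological
    synchrony during a dyadic stress task. Transforms interbeat-interval
    series into continuous respiratory sinus arrhythmia (RSA) and
    epoch-level summaries, estimates per-dyad RSA coupling with a
    baseline-referenced autoregressive model, converts two-wavelength
    fNIRS intensities to oxy-/deoxy-hemoglobin via the modified
    Beer-Lambert law with channel pruning and motion correction, computes
    Morlet wavelet-transform coherence averaged over a frequency band of
    interest, fits affect-by-synchrony moderation models with
    Johnson-Neyman probing, and validates neural synchrony against a
    random-pairing permutation control. Includes a seeded synthetic
    cohort generator so every stage can be exercised and calibrated
    without access to human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
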