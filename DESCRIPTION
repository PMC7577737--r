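Package: corticalwaves
Title: Quantification of Cortical Travelling Waves in Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies forward (posterior-to-anterior) and
    backward (anterior-to-posterior) travelling waves in multichannel EEG.
    Sliding one-second time-by-electrode maps are decomposed with a 2D FFT;
    energy in opposite signed-frequency quadrants measures waves travelling
    in opposite directions along an ordered electrode array, and an
    electrode-shuffled surrogate null converts each quadrant maximum into a
    net wave amount in decibel. Includes preprocessing (zero-phase band-pass,
    average reference, array selection, sliding windows), per-frequency wave
    spectra and peak-frequency band histograms, readers for BrainVision and
    EDF recordings, a synthetic pharmaco-EEG study generator with calibrated
    wave content, and the study-level statistics used in drug-versus-placebo
    designs (minute-wise t-tests with false discovery rate correction,
    forward-backward coupling, rating correlations, a default-prior Bayes
    factor, and two-sample power analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
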