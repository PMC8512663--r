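Package: tscseeg
Title: EEG Artifact Suppression and Evaluation During Transcutaneous Spinal Cord Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates multi-channel EEG/EMG recordings contaminated by
    transcutaneous spinal cord stimulation (tSCS) pulse-train artifacts,
    suppresses the artifact with four filters (superposition of moving
    averages, self-referenced adaptive, median, and band-stop), and
    evaluates contamination and recovery in the time domain (kurtosis, RMS,
    Higuchi fractal dimension, zero crossings), the frequency domain
    (multitaper spectra, 30 Hz topography, individual alpha frequency), and
    through sensorimotor-rhythm movement classification (CSP + LDA with
    cross-validation and binomial chance levels). Includes EDF/EDF+ input
    and output and a non-parametric factorial testing layer
    (Scheirer-Ray-Hare, gated pairwise tests, FDR correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
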