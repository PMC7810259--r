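Package: modtrf
Title: Modulation-Spectrum Stimuli and Temporal Response Function Encoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the long-term modulation spectrum of
    sounds shapes auditory EEG responses. Synthesizes amplitude-modulated
    noise with 1/f or speech-like modulation spectra (inverse-FFT method
    with random phases, Butterworth envelope conditioning, 100% modulation
    depth, embedded probe tones at fixed SNR), extracts cochlear envelopes
    through a gammatone filterbank, estimates modulation spectra and their
    spectral exponents, computes tone-detection sensitivity (d-prime) and
    local signal-to-noise ratios in short temporal windows, preprocesses
    multi-channel EEG epochs with PCA auditory-component spatial filtering,
    Morlet induced power, and band-limited decompositions, and fits
    ridge-regression temporal response functions (TRFs) with
    cross-validated regularization, Fisher-z prediction scoring,
    cross-encoding matrices, and label-shuffling permutation thresholds.
    A synthetic-data module generates EEG and behavioral recordings with
    known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
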