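# modtrf

Tools for studying how the **long-term modulation spectrum** of a sound
shapes auditory EEG responses — for auditory neuroscientists and
psychoacousticians who work with amplitude-modulated (AM) stimuli,
envelope-tracking (temporal response function, TRF) models, or both.

Natural sounds differ in how their amplitude envelopes distribute energy
across temporal rates: modulation amplitude spectra follow roughly
`A(f) ∝ f^(−χ)`, with speech near χ ≈ 1–1.5 and a syllabic peak near
4 Hz. The package implements a complete analysis chain around that
observation:

* **Stimulus synthesis** — AM noise with 1/f modulation spectra
  (χ ∈ {0.5, 0.75, 1, 1.5, 2}) or a speech-shaped spectrum, via
  inverse-FFT synthesis with random phases, Butterworth envelope
  conditioning (1–30 Hz), exact 100% modulation depth, and embedded
  1-kHz probe tones at −10 dB global SNR (60 stimuli per type, half
  probed).
* **Acoustics** — 32-band gammatone filterbank (80–8000 Hz, log-spaced),
  Hilbert band envelopes, mean modulation spectra with fitted 2–20 Hz
  exponents, and the local SNR of each probe tone in nine rectangular
  windows (30–500 ms) centered on the tone.
* **Behavior** — d′ from yes/no confusion tables with the half-trial
  correction for perfect tables, and per-window d′-vs-local-SNR
  correlations (Fisher z before averaging).
* **EEG** — zero-phase 1–45 Hz FIR preprocessing, baseline correction,
  PCA auditory-component spatial filtering of the evoked response,
  neural-band decomposition (δ, θ, α, β, γ), onset/offset evoked
  responses, and Morlet induced power (1–45 Hz, 2→10 cycles, dB re
  −1…−0.75 s baseline).
* **TRF encoding** — forward ridge regression
  `k = (XᵀX + λM)⁻¹ Xᵀy` on a lagged envelope design (0–500 ms lags at
  128 Hz), cross-validated λ selection (leave-one-out over trials or
  10-fold over segments), Fisher-z prediction scoring, six-by-six
  cross-encoding matrices, and modulation-band × neural-band resolved
  encoding (2-Hz steps).
* **Permutation statistics** — within-participant label shuffling with
  median-summary (global threshold) and mean-summary (per-cell
  thresholds) schemes at one-sided α = 0.05/0.01.
* **Synthetic data** — EEG generated from known tri-phasic kernels and a
  known topography plus 1/f noise at a configurable response SNR, and a
  logistic tone-detection observer reading 30-ms local SNR, so the whole
  chain is testable with ground truth.

## Worked example

```r
library(modtrf)

# a small stimulus set: two 1/f exponents, 6 stimuli each, half probed
set <- build_stimulus_set(master_seed = 7, exponents = c(0.5, 2),
                          include_speech = FALSE, n_per_type = 6)
print(set)
#> AM stimulus set: 12 stimuli, 2 types ( e0.5, e2 )
#> probed: 6 of 12

# recover the generating exponents from the synthesized envelopes
type_modulation_spectra(set, source = "envelope")
#>   am_type exponent_fit
#> 1    e0.5    0.5464998
#> 2      e2    2.0926059

# local SNR of the first probed stimulus in the nine analysis windows
probed <- which(!is.na(set$manifest$probe_onset_s))[1]
print(local_snr(set$stimuli[[probed]]), digits = 3)
#>   window_ms snr_db
#> 1        30  -11.3
#> 2        50  -11.2
#> ...
#> 9       500  -10.6

# tone-detection sensitivity with the half-trial correction
dprime_from_responses(hits = 30, misses = 0, false_alarms = 0,
                      correct_rejections = 30)$dprime
#> [1] 4.25609
```

The fitted exponents recover the generating χ from only six
realizations; the probed stimulus shows how the *local* SNR wanders
around the −10 dB global calibration depending on where the tone landed
in the envelope.

## The analysis workflow

The `analysis/` scripts run the full study pipeline on synthetic data
and write compact tables under `results/`:

| script | what it does |
|---|---|
| `01_stimuli.R` | builds the 360-stimulus set, checks depth/SNR invariants, envelope exponent fits |
| `02_acoustics.R` | gammatone modulation spectra and the type × window local-SNR matrix |
| `03_behavior.R` | logistic-observer cohorts, d′ tables, group permutation threshold, d′–SNR window profile |
| `04_eeg.R` | simulated 62-channel session, PCA component, evoked responses, induced power |
| `05_trf.R` | per-type TRFs with λ selection, kernel recovery, cross-encoding matrix with permutation flags |
| `06_modulation_bands.R` | modulation-band × neural-band encoding grid |

With the default seed the workflow reproduces the qualitative findings
the design targets: d′ is highest for the steepest (χ = 2) modulation
spectrum and exceeds the α = 0.01 permutation threshold; the d′–SNR
correlation declines from short to long analysis windows; TRF kernels
are recovered at r = 0.94–0.98 from 0 dB EEG; and the cross-encoding
matrix is significant only on its diagonal — the TRFs are specific to
the modulation spectrum they were trained on.

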