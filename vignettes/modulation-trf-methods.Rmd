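---
title: "Methods: modulation-spectrum stimuli and TRF encoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modulation-spectrum stimuli and TRF encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `modtrf`. The package implements an analysis chain for
studying how the long-term modulation spectrum of a sound shapes auditory
EEG responses: parametric amplitude-modulated (AM) stimulus synthesis,
cochlear-envelope acoustics, tone-detection behavior with a local-SNR
account, EEG auditory-component extraction, and ridge temporal response
function (TRF) encoding with permutation statistics. A synthetic-data
module generates EEG and behavioral recordings with known ground truth so
that every stage can be validated end to end without human data.

## Stimulus synthesis

An AM envelope is synthesized by inverse FFT from a one-sided modulation
amplitude spectrum with phases drawn uniformly on $[0, 2\pi)$
(conjugate-symmetrized). The spectrum is either a 1/f shape,
$A(f) \propto f^{-\chi}$ with exponents $\chi \in \{0.5, 0.75, 1, 1.5,
2\}$, or an empirical speech-shaped spectrum obtained by averaging FFT
magnitudes of broadband speech envelopes. Two conventions deserve
emphasis:

* **The exponent applies to the amplitude spectrum, not the power
  spectrum.** Modulation spectra in this literature are plotted and
  fitted as FFT magnitude; the power-spectral exponent would be $2\chi$.
* **The DC bin is set to zero** before the inverse transform: a 1/f
  amplitude diverges at $f = 0$, and the mean level is re-imposed anyway
  by depth normalization.

The synthesis grid is 10 s at 20 kHz. The raw envelope is conditioned
with a forward high-pass Butterworth (order 3 at 1 Hz) and low-pass
Butterworth (order 6 at 30 Hz); the middle 5 s are kept, which discards
the filter transients at both edges, and the segment is normalized to
exactly 100% modulation depth (minimum 0, maximum 1). The stimulus is
this envelope times a fresh standard-normal white-noise carrier, with
50-ms raised-cosine ramps and a configurable target RMS (default 0.05;
presentation level in pascals is a hardware quantity that digital
synthesis cannot fix).

Half of the 60 stimuli per type carry a 1000-Hz, 30-ms probe tone with
10-ms ramps, summed onto the masker at an onset drawn uniformly from
0.75-4.25 s. The tone is scaled so that its mean-square power over its
own duration, relative to the long-term mean-square power of the whole
5-s masker, is $-10$ dB. This global convention makes the nominal SNR
identical for every stimulus while the *local* SNR at the tone's position
varies with the envelope — the variable the behavioral analysis exploits.

## Acoustics

Cochlear envelopes are computed with a fourth-order FIR gammatone
filterbank, $g(t) = t^{3} e^{-2\pi b t} \cos(2\pi f_c t)$ with
$b = 1.019\,\mathrm{ERB}(f_c)$, 32 center frequencies log-spaced from 80
to 8000 Hz and unit peak gain per band. Kernels are truncated at 102.4 ms
(the 80-Hz band has decayed by $e^{-20}$ there) and applied in the
frequency domain; the Hilbert envelope is obtained in the same inverse
FFT by zeroing negative frequencies. The broadband envelope is the
unweighted mean across bands (the source text does not state band
weights; equal weighting is the natural reading).

Modulation spectra are estimated as the arithmetic mean across stimuli of
the FFT magnitude of each demeaned, **Hann-tapered** envelope. The taper
is an estimator choice worth explaining: the 5-s analysis segment is cut
from a 10-s synthesis grid, so the synthesis bins fall between analysis
bins and a rectangular window leaks energy from the dominant
low-frequency modulations into the tail. For $\chi = 2$ the measured
2-20 Hz slope of the conditioned envelopes is about $-1.7$ with a
rectangular window and $-2.0$ with the Hann taper; the taper therefore
recovers the quantity the synthesis actually put in.

The 2-20 Hz exponent is the negated least-squares slope of
$\log_{10}$ amplitude on $\log_{10}$ frequency. On the synthesized
envelopes all five exponents are recovered within $\pm 0.05$. Through the
gammatone path the recovery is exact only for $\chi \le 1$: the white
noise carrier contributes intrinsic envelope fluctuations (the Hilbert
envelope of narrowband noise fluctuates on the scale of the band's
bandwidth), which form a broadband floor in the 2-20 Hz range of the
broadband-envelope spectrum. Once the prior amplitude tail has fallen by
$10^{-\chi}$ below its 2-Hz value, the floor dominates, and the measured
slopes for $\chi = 1.5$ and $2$ flatten to roughly $-1.2$ and $-1.0$.
This is a physical property of the construction, not an estimator
artifact — the same estimator recovers the envelope-level slopes — and it
is why the preserved "trend" of measured modulation spectra should be
read qualitatively for steep exponents.

Local SNR divides the tone's mean-square power (computed from the known,
ramped probe waveform) by the masker's mean-square power in a rectangular
window centered 15 ms after tone onset, in dB, for the nine window sizes
30-500 ms. Windows are rectangular and untapered; windows that would
cross the stimulus edge are clipped with a warning.

## Behavior

For each AM type the yes/no responses form a 2x2 confusion table and
$d' = \Phi^{-1}(\text{hit rate}) - \Phi^{-1}(\text{FA rate})$. Only a
fully perfect table (no misses *and* no false alarms) receives the
half-trial correction (0.5 added to both error cells, keeping the margins
fixed); a table with a single perfect margin is left untouched and
produces an error, which `dprime_table(on_boundary = "drop")` can convert
into dropping that cell. The per-window behavioral correlation computes,
per participant, the Pearson correlation across the six types between
$d'$ and the type-mean local SNR at that window, and averages Fisher-z
transforms across participants (z before mean, always; $|r| = 1$ is
clipped at $1 - 10^{-12}$).

## EEG pipeline

Epochs (trials x channels x samples, 500 Hz, $-3$ to $+8$ s around
onset) are average-referenced, band-passed 1-45 Hz with a zero-phase FIR
(order 550; the symmetric kernel's linear phase is removed exactly in the
frequency domain, so a single pass is zero-phase), and baseline-corrected
by the $-1$ to 0 s mean. The auditory component is the first principal
component of the grand-average evoked response over 0-500 ms across all
AM trials; its polarity is chosen automatically so the projected evoked
response is positive on average over 150-350 ms (the canonical auditory
positivity near 250 ms), replacing a manual polarity check. Neural bands
($\delta$ 1-3, $\theta$ 4-7, $\alpha$ 8-12, $\beta$ 13-30, low-$\gamma$
31-45 Hz) use two-pass Butterworth filters of order 4. Induced power uses
Morlet wavelets from 1 to 45 Hz in 1-Hz steps with window length
increasing linearly from 2 to 10 cycles, trial-averaged power normalized
by the $-1$ to $-0.75$ s baseline mean per frequency, in dB, and the
induced spectrum averages 0.5-4.5 s to avoid onset/offset transients.

## TRF encoding

The forward model predicts the neural response as a convolution of the
stimulus envelope with a lag-resolved kernel. The lagged design matrix
holds the envelope at lags 0-500 ms (every sample at the working rate,
128 Hz), zero-padded at trial edges, with an unpenalized intercept.
Envelopes are z-scored and responses centered per trial; design columns
are also centered per trial so that centering commutes with the linear
model (zero-padded edges otherwise leave per-trial offsets no single
intercept can absorb). The ridge solution is
$\hat k = (X^\top X + \lambda M)^{-1} X^\top y$ with $M$ the identity
with a zero for the intercept. The printed estimator in the source
literature has the form of a backward model while its reconstruction
equation is forward; this package implements the forward form throughout.

The envelope regressor is band-matched to the response with the *same*
zero-phase FIR used in preprocessing before downsampling. This matters:
the regressor otherwise carries sub-1-Hz content that the filtered
response cannot contain, and because the slow-spectrum stimuli
concentrate their energy exactly there, even a well-intentioned
Butterworth high-pass at the working rate (whose edge response differs
from the FIR's) biased kernel estimates badly in validation.

$\lambda$ is selected on a log-spaced grid $10^{-2}\ldots10^{6}$ (17
points) by leave-one-out cross-validation over trials (10-fold over
segments for continuous material), maximizing the mean held-out Fisher-z
score. In these data the CV curve is flat over roughly six decades:
prediction is noise-limited and cannot distinguish models, while weakly
regularized kernels are visibly noisy. Ties are therefore broken toward
the strongest regularization among lambdas whose deficit from the
maximum is within one standard error of the paired fold-wise difference
or below 0.01 z (a region of practical equivalence). The literal argmax
remains available (`selection = "max"`) and is used for noiseless
validation runs, where regularization is unnecessary and the argmax
naturally lands at the small-$\lambda$ end.

Cross-encoding scores each type's TRF (refit on all its trials at its
training $\lambda$; no re-selection on test data) on every other type's
trials, per-trial z averaged; diagonal cells are the own-type held-out
performance, the transfer upper bound. The first 0.5 s of every trial is
excluded from fitting and scoring so that onset-evoked transients, which
the stationary envelope kernel cannot explain, stay out of the
regression. The modulation-band decomposition filters envelopes into 22
bands of 2 Hz width (1-45 Hz, two-pass Butterworth order 2) and repeats
training per modulation x neural band; the matched-band summary averages
each neural band over the modulation bands overlapping its passband.

## Permutation statistics

Condition labels are shuffled independently within each participant,
never across participants. Two summaries mirror the two uses: the
behavioral test summarizes each permuted dataset by the mean over
conditions of the per-condition median across participants (one global
threshold); the cross-encoding test uses per-cell means across
participants (per-cell thresholds). One-sided thresholds are the
$\lceil (1-\alpha)(n_{\text{perm}}+1) \rceil$-th order statistics of the
permutation distribution — the exact-test convention counting the
observed dataset — giving a null flag rate of $10/201 \approx 0.0497$ at
$n_{\text{perm}} = 200$ and $50/1001 \approx 0.050$ at 1000. (The naive
$\lceil (1-\alpha) n_{\text{perm}} \rceil$ convention is anti-conservative,
with a flag rate of $0.0547$ at 200 permutations; calibration runs catch
the difference.)

## The synthetic-data generator

The generator realizes the forward model the analysis assumes, so that
pipeline closure is a meaningful test:

* **Kernels** are tri-phasic (P1-N1-P2-like) difference-of-gamma shapes
  on the 0-500 ms lag grid. In `"specific"` mode the six types receive
  distinct latencies, widths and lobe ratios, chosen (once) so that all
  pairwise correlations stay below 0.5 while every kernel keeps the same
  leading polarity and remains band-limited below the 30-Hz ceiling of
  the conditioned envelopes — components above that ceiling would be
  unidentifiable from these stimuli by construction. Kernels are ordered
  so that steeper-spectrum types receive slower, broader kernels, the
  matched-receptive-field structure the encoding analysis is designed to
  detect. `"shared"` mode gives every type the same canonical kernel.
* **Topography** is a smooth zero-sum unit-norm pattern (two opposed
  Gaussian bumps over the channel index). Zero-sum is what
  average-referenced EEG can represent; an all-positive pattern would be
  partially destroyed by re-referencing and could never be recovered.
* **Onset response.** Every trial additionally receives a
  type-independent P1-N1-P2 onset transient (amplitude `onset_gain = 2`
  times the envelope-driven component's SD). Real auditory recordings
  are dominated by such onset responses — they are the reason the
  PCA-on-evoked spatial filter works — and without one the evoked
  response of random-phase AM trials is weak and the filter estimate
  fragile. The onset window is excluded from TRF fitting, as above.
* **Noise** is 1/f-amplitude-spectrum Gaussian noise (exponent 1),
  independent across channels, scaled so that the variance ratio of the
  envelope-driven component to topography-projected noise matches the
  configured response SNR (0 dB by default; `Inf` switches noise off).
* **Behavior** is a logistic observer reading each probe's local SNR in
  a 30-ms integration window: threshold $-8$ dB, slope 4 dB, false-alarm
  rate 0.25. The slope is deliberately set commensurate with the
  within-type spread of local SNR so that detection probability varies
  over the whole stimulus range instead of saturating; rates well off
  the 0/1 boundaries also keep the 2x2 tables non-degenerate under the
  strict correction convention. The observer is a first-order account:
  real listeners add criterion drift, lapses and learning that this
  generator does not model.

What passing closure tests does and does not show: recovery of kernels
(r > 0.9 at 0 dB with 50 trials/type), topography
($|\cos| > 0.95$) and cross-encoding specificity demonstrates that the
pipeline is correct *under its own generative assumptions* — linear
envelope-driven responses, stationary kernels, additive 1/f noise. It
does not certify performance on real EEG, where artifacts,
non-stationarity and nonlinear cochlear processing intervene.

## Problem sizes and numerical notes

Validation analyses use the full stimulus construction (60 stimuli per
type at 20 kHz; exponent recovery is measured on all 60 realizations per
type) and, for EEG closure, 50 trials per type on 62 channels with
epochs trimmed to $-1.5$ to $+6.5$ s (covering the baseline and the full
stimulus; the canonical $-3$ to $+8$ s frame is the container default).
Permutation calibration uses 1000 simulated null datasets at 200
permutations each; behavioral closure averages five cohorts of 19
simulated participants. Fourier resampling (`resample_fft`) is exact for
band-limited signals and is used at integer sample-count ratios
(20 kHz to 500 and 128 Hz over 5-s and 11-s windows).

Two validation findings are themselves results worth knowing about.
First, the gammatone-path exponent recovery fails for $\chi \ge 1.5$ for
the physical reason described above; the corresponding check is expected
to fail and documents the measured slopes. Second, the strict claim that
the d'-SNR correlation peaks exactly at the 30-ms window is knife-edged:
a dense probe Monte Carlo puts the population correlation at 0.9950
(30 ms) vs 0.9954 (50 ms), so the realized argmax depends on the stimulus
sample, while the decreasing shape of the profile (30 ms versus 500 ms)
is robust. The logistic observer's nonlinear summary of a within-type
SNR spread (~9 dB) that dwarfs the between-type spread (~3 dB) is the
cause — an instructive reminder that "the short window explains behavior
best" is a statement about a profile's shape, not a razor-sharp maximum.

## Known limitations

* Presentation-level calibration (dB SPL) is out of reach of digital
  synthesis; stimulus level is a digital RMS.
* The gammatone filterbank uses log-spaced center frequencies (not
  ERB-spaced) and no compressive nonlinearity.
* The speech-derived modulation spectrum ships with synthetic surrogate
  speech envelopes (1/f^1.5 with a 4-Hz syllabic peak); supply real
  broadband speech envelopes to `build_stimulus_set(speech_reference =
  ...)` for an empirical spectrum.
* Artifact handling (ICA, trial rejection) is not implemented; the
  generator produces clean data, and `preprocess_eeg` only drops trials
  with non-finite samples.
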