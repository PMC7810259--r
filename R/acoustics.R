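#' Gammatone filterbank (FIR, frequency domain)
#'
#' Fourth-order gammatone filters `t^3 exp(-2 pi b t) cos(2 pi cf t)` with
#' 32 center frequencies log-spaced from 80 to 8000 Hz and bandwidth
#' `b = 1.019 * ERB(cf)`. Kernels are truncated FIRs held as frequency
#' responses (peak gain normalized to 1) so that filtering and Hilbert
#' envelope extraction happen in a single inverse FFT per band.
#'
#' @param fs Sample rate in Hz (>= 16000 for the default 8-kHz top band).
#' @param nfft FFT length the bank is bound to (must cover signal + kernel).
#' @param n_bands Number of bands (default 32).
#' @param f_lo,f_hi Lowest/highest center frequency in Hz (80, 8000).
#' @param kernel_s Kernel truncation length in seconds (default 0.1024,
#'   comfortably past the ringing of the 80-Hz band).
#' @return A `gammatone_bank` with complex frequency-response matrix `G`
#'   (`nfft` x `n_bands`), `center_frequencies`, `fs`, `nfft`.
#' @export
gammatone_bank <- function(fs, nfft, n_bands = 32, f_lo = 80, f_hi = 8000,
                           kernel_s = 0.1024) {
  stopifnot(fs >= 2 * f_hi)
  L <- round(kernel_s * fs)
  stopifnot(nfft >= L)
  cfs <- exp(seq(log(f_lo), log(f_hi), length.out = n_bands))
  t <- (0:(L - 1)) / fs
  G <- matrix(complex(real = 0), nfft, n_bands)
  for (j in seq_len(n_bands)) {
    cf <- cfs[j]
    b <- 1.019 * 24.7 * (4.37 * cf / 1000 + 1)
    g <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * cf * t)
    Gf <- stats::fft(c(g, numeric(nfft - L)))
    G[, j] <- Gf / max(Mod(Gf))
  }
  structure(list(G = G, center_frequencies = cfs, fs = fs, nfft = nfft,
                 kernel_len = L),
            class = "gammatone_bank")
}

#' Cochlear envelope of a waveform
#'
#' Filters the waveform through the gammatone filterbank and extracts the
#' Hilbert envelope (modulus of the analytic signal) of each band; the
#' broadband envelope is the arithmetic mean across bands.
#'
#' @param waveform Numeric vector.
#' @param fs Sample rate in Hz (>= 16000).
#' @param bank Optional pre-built `gammatone_bank` (its `nfft` must cover
#'   `length(waveform) + kernel length`); built on the fly otherwise.
#' @param keep_bands Keep the per-band envelope matrix (default TRUE; set
#'   FALSE to save memory when only the broadband envelope is needed).
#' @return A `cochlear_envelope` with `band_envelopes` (bands x time, or
#'   NULL), `center_frequencies`, `broadband`, `fs`.
#' @export
cochlear_envelope <- function(waveform, fs, bank = NULL, keep_bands = TRUE) {
  stopifnot(fs >= 16000)
  n <- length(waveform)
  if (is.null(bank)) {
    bank <- gammatone_bank(fs, nfft = next_pow2(n + round(0.1024 * fs)))
  }
  stopifnot(inherits(bank, "gammatone_bank"), bank$fs == fs)
  if (n < bank$kernel_len) stop("waveform shorter than the filter settle length")
  nfft <- bank$nfft
  stopifnot(nfft >= n + bank$kernel_len)
  X <- stats::fft(c(waveform, numeric(nfft - n)))
  h <- numeric(nfft)
  h[1] <- 1; h[nfft / 2 + 1] <- 1; h[2:(nfft / 2)] <- 2
  Xa <- X * h
  nb <- ncol(bank$G)
  bands <- if (keep_bands) matrix(0, nb, n) else NULL
  broadband <- numeric(n)
  for (j in seq_len(nb)) {
    env <- Mod(stats::fft(Xa * bank$G[, j], inverse = TRUE) / nfft)[1:n]
    if (keep_bands) bands[j, ] <- env
    broadband <- broadband + env
  }
  broadband <- broadband / nb
  structure(list(band_envelopes = bands,
                 center_frequencies = bank$center_frequencies,
                 broadband = broadband, fs = fs),
            class = "cochlear_envelope")
}

#' Average modulation spectrum of a set of envelopes
#'
#' Computes the one-sided FFT magnitude spectrum of each envelope (demeaned,
#' Hann-tapered) and averages the magnitudes arithmetically across inputs.
#'
#' @param envelopes List of equal-length numeric envelopes (or a single
#'   numeric vector).
#' @param fs Sample rate in Hz.
#' @param taper Taper passed to [magnitude_spectrum()] (default `"hann"`).
#' @return A `modulation_spectrum_estimate` with `frequencies`,
#'   `amplitudes`, `n_averaged`.
#' @export
modulation_spectrum_estimate <- function(envelopes, fs, taper = "hann") {
  if (is.numeric(envelopes)) envelopes <- list(envelopes)
  if (length(envelopes) == 0) stop("no envelopes supplied")
  lens <- vapply(envelopes, length, integer(1))
  if (length(unique(lens)) != 1) stop("envelopes must have equal length")
  acc <- NULL
  for (e in envelopes) {
    m <- magnitude_spectrum(as.numeric(e), fs, taper = taper)
    acc <- if (is.null(acc)) m$amplitudes else acc + m$amplitudes
  }
  structure(list(frequencies = m$frequencies,
                 amplitudes = acc / length(envelopes),
                 n_averaged = length(envelopes)),
            class = "modulation_spectrum_estimate")
}

#' Fit the 1/f exponent of a modulation spectrum
#'
#' Least-squares slope of `log10(amplitude)` on `log10(frequency)` over
#' `[f_lo, f_hi]`, negated so that a `f^-chi` spectrum returns `chi`.
#'
#' @param estimate A `modulation_spectrum_estimate` (or any list with
#'   `frequencies` and `amplitudes`).
#' @param f_lo,f_hi Fit range in Hz (defaults 2 and 20), both > 0.
#' @return The fitted exponent (dimensionless).
#' @export
fit_exponent <- function(estimate, f_lo = 2, f_hi = 20) {
  stopifnot(f_lo > 0, f_lo < f_hi)
  f <- estimate$frequencies
  a <- estimate$amplitudes
  sel <- which(f >= f_lo & f <= f_hi & a > 0)
  if (length(sel) < 3) stop("fewer than 3 usable bins in the fit range")
  fit <- stats::lm.fit(cbind(1, log10(f[sel])), log10(a[sel]))
  -unname(fit$coefficients[2])
}

#' Local SNR of a probe tone in an AM masker
#'
#' For each window size, centers a rectangular temporal window in the
#' middle of the tone (15 ms after tone onset for the default 30-ms tone)
#' and returns `10 * log10(tone power / masker power in the window)`, where
#' the tone power is the mean square of the analytically known ramped probe
#' waveform over its duration and the masker power is the mean square of
#' the AM waveform (probe excluded) within the window. Windows that would
#' extend past the stimulus edges are clipped with a warning.
#'
#' @param masker Numeric AM waveform without the probe, or an
#'   `am_stimulus`; if a probed `am_stimulus` is given, the probe waveform
#'   is subtracted out first.
#' @param probe Probe descriptor (as stored by [insert_tone()]); taken from
#'   the stimulus if missing.
#' @param window_sizes Window sizes in ms (default
#'   `c(30, 50, 70, 100, 150, 200, 250, 350, 500)`).
#' @param fs Sample rate in Hz (taken from the stimulus if given).
#' @return A data frame with `window_ms` and `snr_db`.
#' @export
local_snr <- function(masker, probe = NULL,
                      window_sizes = c(30, 50, 70, 100, 150, 200, 250, 350, 500),
                      fs = NULL) {
  if (inherits(masker, "am_stimulus")) {
    st <- masker
    fs <- st$fs
    if (is.null(probe)) probe <- st$probe
    if (is.null(probe)) stop("stimulus has no probe metadata")
    masker <- st$waveform
    i0 <- round(probe$onset * fs) + 1
    tone <- probe_waveform(probe, fs)
    masker[i0:(i0 + length(tone) - 1)] <-
      masker[i0:(i0 + length(tone) - 1)] - tone
  }
  stopifnot(!is.null(probe), !is.null(fs))
  n <- length(masker)
  tone <- probe_waveform(probe, fs)
  tone_power <- mean(tone^2)
  center <- round((probe$onset + probe$duration / 2) * fs) + 1
  snr <- vapply(window_sizes, function(wms) {
    half <- round(wms / 1000 * fs / 2)
    lo <- center - half
    hi <- center + half - 1
    if (lo < 1 || hi > n) {
      warning("window of ", wms, " ms clipped to the stimulus edges")
      lo <- max(lo, 1)
      hi <- min(hi, n)
    }
    p <- mean(masker[lo:hi]^2)
    if (p == 0) stop("zero masker power in the ", wms, " ms window")
    10 * log10(tone_power / p)
  }, numeric(1))
  data.frame(window_ms = window_sizes, snr_db = snr)
}
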