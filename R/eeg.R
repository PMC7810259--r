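#' Conventional EEG frequency bands
#'
#' delta 1-3, theta 4-7, alpha 8-12, beta 13-30, gamma (low) 31-45 Hz,
#' plus the full 1-45 Hz range.
#'
#' @param include_full Include the `full` band (default TRUE).
#' @return Named list of `c(lo, hi)` passbands in Hz.
#' @export
neural_bands <- function(include_full = TRUE) {
  b <- list(delta = c(1, 3), theta = c(4, 7), alpha = c(8, 12),
            beta = c(13, 30), gamma = c(31, 45))
  if (include_full) b$full <- c(1, 45)
  b
}

#' Construct an EEG epochs container
#'
#' @param data Numeric array trials x channels x samples (microvolts).
#' @param fs Sampling rate in Hz (default 500).
#' @param t0 Stimulus-onset time within the epoch, in s (default 3).
#' @param trial_meta Data frame of per-trial metadata (e.g. `am_type`).
#' @param channel_names Optional channel names.
#' @return An `eeg_epochs` object.
#' @export
eeg_epochs <- function(data, fs = 500, t0 = 3, trial_meta = NULL,
                       channel_names = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(dim(data)[2]))
  }
  if (is.null(trial_meta)) {
    trial_meta <- data.frame(trial = seq_len(dim(data)[1]))
  }
  stopifnot(nrow(trial_meta) == dim(data)[1],
            length(channel_names) == dim(data)[2])
  structure(list(data = data, fs = fs, t0 = t0, trial_meta = trial_meta,
                 channel_names = channel_names),
            class = "eeg_epochs")
}

epoch_times <- function(x) (seq_len(dim(x$data)[length(dim(x$data))]) - 1) / x$fs - x$t0

#' Preprocess EEG epochs
#'
#' Re-references to the channel average, band-pass filters 1-45 Hz with a
#' zero-phase (forward-reverse) FIR filter, and subtracts the per-trial,
#' per-channel mean of the -1 to 0 s baseline window. Trials containing
#' non-finite samples are dropped with a message.
#'
#' @param epochs An `eeg_epochs` object.
#' @param band Passband in Hz (default `c(1, 45)`).
#' @param fir_order FIR order (default 550 at 500 Hz, ~3 Hz transition).
#' @param baseline Baseline window in s relative to onset (default
#'   `c(-1, 0)`).
#' @param average_reference Re-reference to the channel mean (default TRUE).
#' @return The filtered, baseline-corrected `eeg_epochs`.
#' @export
preprocess_eeg <- function(epochs, band = c(1, 45), fir_order = 550,
                           baseline = c(-1, 0), average_reference = TRUE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- epochs$data
  bad <- which(apply(d, 1, function(tr) any(!is.finite(tr))))
  if (length(bad)) {
    message("dropping ", length(bad), " trial(s) with non-finite samples")
    d <- d[-bad, , , drop = FALSE]
    epochs$trial_meta <- epochs$trial_meta[-bad, , drop = FALSE]
  }
  nt <- dim(d)[1]; nc <- dim(d)[2]; ns <- dim(d)[3]
  A <- zero_phase_fir_response(ns, epochs$fs, band, fir_order)
  t <- (seq_len(ns) - 1) / epochs$fs - epochs$t0
  bsel <- t >= baseline[1] & t < baseline[2]
  for (i in seq_len(nt)) {
    tr <- d[i, , , drop = TRUE]
    if (nc == 1) tr <- matrix(tr, 1, ns)
    if (average_reference && nc > 1) {
      tr <- sweep(tr, 2, colMeans(tr))
    }
    for (j in seq_len(nc)) {
      x <- apply_fir_response(tr[j, ], A)
      d[i, j, ] <- x - mean(x[bsel])
    }
  }
  epochs$data <- d
  epochs$preprocessed <- list(band = band, fir_order = fir_order,
                              baseline = baseline)
  epochs
}

#' Fit the PCA auditory-component spatial filter
#'
#' Averages all trials into the evoked response, restricts it to 0-500 ms
#' after stimulus onset, and takes the first principal component across
#' channels as a spatial filter. The sign is chosen automatically so that
#' the projected evoked response is positive on average between 150 and
#' 350 ms after onset (the polarity of the canonical auditory positivity).
#'
#' @param epochs An `eeg_epochs` object (>= 2 channels).
#' @param window PCA window in s after onset (default `c(0, 0.5)`).
#' @param polarity_window Window in s used to fix the sign (default
#'   `c(0.15, 0.35)`).
#' @return A `spatial_filter`: unit-norm `weights` per channel, `polarity`,
#'   `explained_variance_fraction`.
#' @export
fit_spatial_filter <- function(epochs, window = c(0, 0.5),
                               polarity_window = c(0.15, 0.35)) {
  stopifnot(inherits(epochs, "eeg_epochs"), dim(epochs$data)[2] >= 2)
  t <- epoch_times(epochs)
  sel <- t >= window[1] & t <= window[2]
  evoked <- apply(epochs$data[, , sel, drop = FALSE], c(2, 3), mean)
  centered <- evoked - rowMeans(evoked)
  sv <- svd(centered)
  if (sv$d[1] < .Machine$double.eps * 1e3 * max(1, sv$d[1])) {
    stop("rank-deficient evoked matrix; cannot fit a spatial filter")
  }
  w <- sv$u[, 1]
  w <- w / sqrt(sum(w^2))
  proj <- drop(w %*% evoked)
  psel <- t[sel] >= polarity_window[1] & t[sel] <= polarity_window[2]
  polarity <- if (mean(proj[psel]) >= 0) 1 else -1
  structure(list(weights = w, polarity = polarity,
                 explained_variance_fraction = sv$d[1]^2 / sum(sv$d^2),
                 channel_names = epochs$channel_names),
            class = "spatial_filter")
}

#' Project multi-channel epochs through a spatial filter
#'
#' @param epochs An `eeg_epochs` object.
#' @param filter A `spatial_filter` with matching channel count.
#' @return A `component_signal`: `data` (trials x samples), `fs`, `t0`,
#'   `trial_meta`.
#' @export
apply_spatial_filter <- function(epochs, filter) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(filter, "spatial_filter"))
  if (dim(epochs$data)[2] != length(filter$weights)) {
    stop("channel count does not match the spatial filter")
  }
  w <- filter$weights * filter$polarity
  nt <- dim(epochs$data)[1]; ns <- dim(epochs$data)[3]
  out <- matrix(0, nt, ns)
  for (i in seq_len(nt)) {
    out[i, ] <- drop(w %*% epochs$data[i, , , drop = TRUE])
  }
  structure(list(data = out, fs = epochs$fs, t0 = epochs$t0,
                 trial_meta = epochs$trial_meta),
            class = "component_signal")
}

#' Decompose a component signal into frequency bands
#'
#' Zero-phase (forward-reverse) Butterworth band-pass filtering into each
#' requested band (default order 4, the convention for the neural-band
#' filterbank).
#'
#' @param component A `component_signal` (or plain matrix trials x samples
#'   with `fs` supplied).
#' @param bands Named list of `c(lo, hi)` passbands in Hz (default
#'   [neural_bands()]).
#' @param order Butterworth order per pass (default 4).
#' @param fs Sampling rate, required when `component` is a bare matrix.
#' @return Named list of band-limited `component_signal`s.
#' @export
band_decompose <- function(component, bands = neural_bands(), order = 4,
                           fs = NULL) {
  bare <- !inherits(component, "component_signal")
  if (bare) {
    stopifnot(!is.null(fs))
    component <- structure(list(data = rbind(component), fs = fs, t0 = 0,
                                trial_meta = NULL), class = "component_signal")
  }
  nyq <- component$fs / 2
  out <- list()
  for (nm in names(bands)) {
    pb <- bands[[nm]]
    if (any(pb <= 0) || any(pb >= nyq) || pb[1] >= pb[2]) {
      stop("invalid passband for band ", nm)
    }
    bf <- signal::butter(order, pb / nyq, type = "pass")
    bc <- component
    for (i in seq_len(nrow(component$data))) {
      bc$data[i, ] <- as.numeric(signal::filtfilt(bf, component$data[i, ]))
    }
    bc$band <- nm
    bc$passband <- pb
    out[[nm]] <- bc
  }
  out
}

#' Filter a single envelope into one band, zero-phase
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param passband `c(lo, hi)` in Hz.
#' @param order Butterworth order per pass (default 2, the convention for
#'   the modulation-band decomposition).
#' @return Filtered vector.
#' @export
bandpass_envelope <- function(x, fs, passband, order = 2) {
  nyq <- fs / 2
  stopifnot(passband[1] > 0, passband[2] < nyq, passband[1] < passband[2])
  bf <- signal::butter(order, passband / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Evoked response to stimulus onset or offset
#'
#' Trial-averages the component signal in a -200..500 ms window around the
#' event and subtracts the mean of the -200..0 ms pre-event baseline.
#'
#' @param component A `component_signal`.
#' @param event `"onset"` (at `t0`) or `"offset"` (at `t0 + duration`).
#' @param duration Stimulus duration in s (default 5; used for offset).
#' @param window Window in s around the event (default `c(-0.2, 0.5)`).
#' @return List with `times` (s relative to the event) and `response`.
#' @export
evoked_response <- function(component, event = c("onset", "offset"),
                            duration = 5, window = c(-0.2, 0.5)) {
  event <- match.arg(event)
  stopifnot(inherits(component, "component_signal"))
  t_event <- if (event == "onset") 0 else duration
  t <- epoch_times(component) - t_event
  tol <- 0.5 / component$fs
  sel <- which(t >= window[1] - tol & t <= window[2] + tol)
  if (length(sel) < 2 || min(t) > window[1] || max(t) < window[2]) {
    stop("epoch too short for the requested evoked window")
  }
  avg <- colMeans(component$data[, sel, drop = FALSE])
  base <- t[sel] >= -0.2 & t[sel] < 0
  avg <- avg - mean(avg[base])
  list(times = t[sel], response = avg, event = event)
}

# real zero-phase frequency response of a symmetric band-pass FIR: the
# exact linear phase of the fir1 design is removed in the frequency
# domain, so one pass is zero-phase
zero_phase_fir_response <- function(ns, fs, band = c(1, 45),
                                    fir_order = 550) {
  h <- as.numeric(signal::fir1(fir_order, band / (fs / 2), type = "pass"))
  nfft <- next_pow2(ns + length(h))
  Hf <- stats::fft(c(h, numeric(nfft - length(h))))
  shift <- exp(2i * pi * (0:(nfft - 1)) * (fir_order / 2) / nfft)
  Re(Hf * shift)
}

apply_fir_response <- function(x, A) {
  n <- length(x)
  Re(stats::fft(stats::fft(c(x, numeric(length(A) - n))) * A,
                inverse = TRUE))[1:n] / length(A)
}

#' Zero-phase FIR band-pass of a signal
#'
#' The same filter applied to EEG epochs by [preprocess_eeg()], exposed so
#' that stimulus envelopes used as TRF regressors can be matched to the
#' response passband with the identical frequency response.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param band Passband in Hz (default `c(1, 45)`).
#' @param fir_order FIR order (default 550).
#' @return Filtered vector.
#' @export
fir_bandpass <- function(x, fs, band = c(1, 45), fir_order = 550) {
  apply_fir_response(x, zero_phase_fir_response(length(x), fs, band,
                                                fir_order))
}

morlet_wavelet <- function(f, fs, n_cycles) {
  sd_t <- n_cycles / (2 * pi * f)
  half <- ceiling(4 * sd_t * fs)
  t <- (-half:half) / fs
  w <- exp(-t^2 / (2 * sd_t^2)) * exp(1i * 2 * pi * f * t)
  w / sqrt(sum(Mod(w)^2))
}

#' Morlet induced power of a component signal
#'
#' Convolves each trial with complex Morlet wavelets (1-45 Hz in 1-Hz
#' steps, window length increasing linearly from 2 to 10 cycles across
#' that range), averages power across trials, normalizes each frequency by
#' its mean power in the baseline window, and converts to dB. The induced
#' power spectrum is the per-frequency mean over a post-onset averaging
#' window chosen to avoid onset/offset responses.
#'
#' @param component A `component_signal` covering at least -1..4.5 s.
#' @param freqs Frequencies in Hz (default `1:45`).
#' @param cycles Range of wavelet cycles mapped linearly onto `freqs`
#'   (default `c(2, 10)`).
#' @param baseline Baseline window in s (default `c(-1, -0.75)`).
#' @param average_window Spectrum averaging window in s (default
#'   `c(0.5, 4.5)`).
#' @return An `induced_power_result`: `spectrogram` (freq x time, dB),
#'   `times`, `freqs`, `power_spectrum`, `baseline_window`.
#' @export
induced_power <- function(component, freqs = 1:45, cycles = c(2, 10),
                          baseline = c(-1, -0.75),
                          average_window = c(0.5, 4.5)) {
  stopifnot(inherits(component, "component_signal"))
  t <- epoch_times(component)
  if (min(t) > baseline[1] || max(t) < average_window[2]) {
    stop("epoch does not cover the baseline/averaging windows")
  }
  bsel <- t >= baseline[1] & t <= baseline[2]
  if (!any(bsel)) stop("empty baseline window")
  fs <- component$fs
  nt <- nrow(component$data); ns <- ncol(component$data)
  n_cyc <- cycles[1] + (cycles[2] - cycles[1]) *
    (freqs - min(freqs)) / (max(freqs) - min(freqs))
  max_len <- 2 * ceiling(4 * (n_cyc[1] / (2 * pi * freqs[1])) * fs) + 1
  nfft <- next_pow2(ns + max_len)
  Xs <- lapply(seq_len(nt), function(i) {
    stats::fft(c(component$data[i, ], numeric(nfft - ns)))
  })
  pow <- matrix(0, length(freqs), ns)
  for (k in seq_along(freqs)) {
    w <- morlet_wavelet(freqs[k], fs, n_cyc[k])
    L <- length(w)
    W <- stats::fft(c(w, complex(real = numeric(nfft - L))))
    half <- (L - 1) / 2
    for (i in seq_len(nt)) {
      conv <- stats::fft(Xs[[i]] * W, inverse = TRUE) / nfft
      pow[k, ] <- pow[k, ] + Mod(conv[(half + 1):(half + ns)])^2
    }
  }
  pow <- pow / nt
  base_mean <- rowMeans(pow[, bsel, drop = FALSE])
  spec_db <- 10 * log10(pow / base_mean)
  asel <- t >= average_window[1] & t <= average_window[2]
  structure(list(spectrogram = spec_db, times = t, freqs = freqs,
                 power_spectrum = rowMeans(spec_db[, asel, drop = FALSE]),
                 baseline_window = baseline),
            class = "induced_power_result")
}
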