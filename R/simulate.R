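#' Simulation configuration
#'
#' Defaults mirror the recording conditions the analysis expects: 62 scalp
#' channels, 50 analyzed trials per AM type at 500 Hz in a -3..+8 s epoch
#' frame, trial-level response SNR of 0 dB against 1/f-spectrum background
#' noise, and a logistic tone-detection observer reading the local SNR in
#' a 30-ms integration window.
#'
#' @param n_channels Number of EEG channels (default 62).
#' @param n_trials Trials per AM type (default 50).
#' @param fs EEG sampling rate in Hz (default 500).
#' @param epoch_span Epoch window in s relative to onset (default
#'   `c(-3, 8)`).
#' @param response_snr_db Component-to-noise variance ratio in dB after
#'   projection onto the topography (default 0).
#' @param noise_exponent 1/f amplitude-spectrum exponent of the background
#'   noise (default 1).
#' @param psychometric_threshold_db,psychometric_slope_db Logistic observer
#'   threshold and slope on the local-SNR (dB) axis (defaults -8 and 4).
#'   The slope is set commensurate with the within-type spread of local
#'   SNR so that detection probability varies across the whole stimulus
#'   range instead of saturating; this is the regime in which local SNR
#'   measurably drives behavior, the statistical structure the behavioral
#'   analysis assumes.
#' @param false_alarm_rate Yes-rate on tone-absent trials (default 0.25;
#'   near-threshold tone-in-noise detection is hard, and rates well off
#'   the 0/1 boundaries keep every participant-by-type confusion table
#'   non-degenerate for the d-prime convention used here).
#' @param integration_window_ms Observer integration window (default 30).
#' @param master_seed Master seed (default 1).
#' @return Named list of settings.
#' @export
simulation_config <- function(n_channels = 62, n_trials = 50, fs = 500,
                              epoch_span = c(-3, 8), response_snr_db = 0,
                              noise_exponent = 1,
                              psychometric_threshold_db = -8,
                              psychometric_slope_db = 4,
                              false_alarm_rate = 0.25,
                              integration_window_ms = 30,
                              master_seed = 1) {
  as.list(environment())
}

gamma_bump <- function(t, peak_s, width_s) {
  # unimodal bump with mode at peak_s and spread ~ width_s, peak value 1
  shape <- (peak_s / width_s)^2 + 1
  rate <- (shape - 1) / peak_s
  g <- ifelse(t <= 0, 0, t^(shape - 1) * exp(-rate * t))
  g / max(g)
}

triphasic_kernel <- function(lag_s, p1, w1, a2, a3, s2, s3, m2, m3) {
  k <- gamma_bump(lag_s, p1, w1) -
    a2 * gamma_bump(lag_s, p1 + s2 * w1, m2 * w1) +
    a3 * gamma_bump(lag_s, p1 + s3 * w1, m3 * w1)
  k / max(abs(k))
}

# per-type shape table for "specific" mode: P1 latency/width, N1/P2 relative
# amplitudes, latency offsets and width multipliers; chosen so all pairwise
# kernel correlations stay well below 0.5 while every kernel keeps the same
# leading polarity and stays band-limited below ~30 Hz. Rows are ordered
# fast-to-slow so that, with types in the conventional order (shallow to
# steep modulation exponent, speech last), stimuli dominated by slow
# modulations receive slow, broad kernels - the matched-receptive-field
# structure the encoding analysis is designed to detect
specific_kernel_table <- function() {
  data.frame(
    p1 = c(0.044, 0.144, 0.075, 0.109, 0.154, 0.053),
    w1 = c(0.023, 0.024, 0.030, 0.047, 0.045, 0.059),
    a2 = c(1.356, 0.928, 0.527, 0.671, 0.673, 1.423),
    a3 = c(0.635, 1.097, 0.920, 0.683, 0.044, 0.021),
    s2 = c(1.661, 1.906, 2.282, 2.118, 1.996, 1.852),
    s3 = c(4.059, 3.580, 4.180, 4.283, 3.166, 4.312),
    m2 = c(1.985, 1.547, 1.789, 2.009, 1.742, 1.513),
    m3 = c(1.400, 1.436, 1.209, 1.526, 1.307, 1.980))
}

#' Ground-truth TRF kernels for simulation
#'
#' Tri-phasic (P1-N1-P2-like) difference-of-gamma kernels on a lag grid.
#' In `"shared"` mode every AM type receives the same canonical kernel; in
#' `"specific"` mode latencies, widths and lobe amplitudes differ per type
#' so that pairwise kernel correlations are low (all below 0.5 for up to
#' six types) while every kernel keeps the same leading polarity.
#'
#' @param am_types Character vector of type labels.
#' @param fs Sampling rate of the lag grid in Hz (default 500).
#' @param lags_ms Lag window in ms (default `c(0, 500)`).
#' @param mode `"specific"` or `"shared"`.
#' @param amplitude Peak absolute amplitude (default 1).
#' @return Named list of `ground_truth_kernel`s with `kernel`, `lags_ms`,
#'   `params`.
#' @export
make_kernels <- function(am_types, fs = 500, lags_ms = c(0, 500),
                         mode = c("specific", "shared"), amplitude = 1) {
  mode <- match.arg(mode)
  lag_s <- (round(lags_ms[1] / 1000 * fs):round(lags_ms[2] / 1000 * fs)) / fs
  n <- length(am_types)
  if (mode == "shared") {
    tab <- data.frame(p1 = 0.08, w1 = 0.035, a2 = 0.9, a3 = 0.5,
                      s2 = 2.0, s3 = 3.6, m2 = 1.5, m3 = 1.7)
    idx <- rep(1L, n)
  } else {
    tab <- specific_kernel_table()
    idx <- ((seq_len(n) - 1) %% nrow(tab)) + 1
  }
  out <- list()
  for (i in seq_len(n)) {
    r <- tab[idx[i], ]
    if (amplitude == 0) {
      k <- numeric(length(lag_s))
    } else {
      k <- triphasic_kernel(lag_s, r$p1, r$w1, r$a2, r$a3, r$s2, r$s3,
                            r$m2, r$m3)
      if (utils::tail(abs(k), 1) * 15 > max(abs(k))) {
        stop("kernel support exceeds the lag window; widen lags_ms")
      }
      k <- k * amplitude
    }
    out[[am_types[i]]] <- structure(
      list(kernel = k, lags_ms = lag_s * 1000,
           params = c(as.list(r), list(amplitude = amplitude, mode = mode))),
      class = "ground_truth_kernel")
  }
  out
}

#' Canonical auditory onset-response shape
#'
#' A P1-N1-P2 transient over 0-500 ms with a small early positivity, a
#' sharp negativity near 100 ms and a broad dominant positivity near
#' 250 ms, so that the mean over 150-350 ms after onset is positive (the
#' landmark the automatic polarity rule of the spatial filter relies on).
#'
#' @param fs Sampling rate in Hz.
#' @return Numeric vector over 0-0.5 s, peak magnitude 1.
#' @export
onset_response_shape <- function(fs = 500) {
  t <- (0:round(0.5 * fs)) / fs
  k <- 0.5 * gamma_bump(t, 0.055, 0.018) - 0.8 * gamma_bump(t, 0.105, 0.025) +
    gamma_bump(t, 0.25, 0.06)
  k / max(abs(k))
}

#' Ground-truth channel topography
#'
#' A smooth, zero-sum, unit-norm weight pattern over channels (a positive
#' and a negative Gaussian bump over the channel index), standing in for
#' the dipolar scalp projection of the auditory component. Zero-sum
#' patterns are what average-referenced EEG can represent, so the
#' topography is invariant under re-referencing.
#'
#' @param n_channels Number of channels.
#' @param centers Bump centers as fractions of the channel range
#'   (default `c(0.3, 0.75)`; the second bump is negative).
#' @param width Bump width as a fraction of the channel range
#'   (default 0.15).
#' @return Unit-norm, zero-sum numeric vector of length `n_channels`.
#' @export
make_topography <- function(n_channels, centers = c(0.3, 0.75), width = 0.15) {
  idx <- seq(0, 1, length.out = n_channels)
  w <- exp(-(idx - centers[1])^2 / (2 * width^2)) -
    exp(-(idx - centers[2])^2 / (2 * width^2))
  w <- w - mean(w)
  w / sqrt(sum(w^2))
}

one_over_f_noise <- function(n, exponent, seed) {
  amp <- numeric(n)
  fr <- (1:(floor(n / 2)))
  amp[2:(floor(n / 2) + 1)] <- fr^(-exponent)
  if (n %% 2 == 0) {
    amp[(n / 2 + 2):n] <- rev(amp[2:(n / 2)])
  } else {
    amp[(floor(n / 2) + 2):n] <- rev(amp[2:(floor(n / 2) + 1)])
  }
  ph <- with_seed(seed, stats::runif(n, 0, 2 * pi))
  x <- Re(stats::fft(amp * exp(1i * ph), inverse = TRUE))
  (x - mean(x)) / stats::sd(x)
}

#' Simulate multi-channel EEG epochs from known kernels
#'
#' Realizes the forward encoding model: the component time course of each
#' trial is the sum over bands of the band-filtered stimulus envelope
#' convolved with that band's ground-truth kernel; channels are the
#' topography times the component plus 1/f-spectrum Gaussian noise scaled
#' so that the variance ratio of component to topography-projected noise
#' matches `config$response_snr_db`.
#'
#' @param envelopes List of per-trial stimulus envelopes at `config$fs`
#'   (stimulus period only; placed at the epoch's onset).
#' @param kernels Either a named list of `ground_truth_kernel`s (one per
#'   trial label, broadband drive) or a list of such lists keyed by band
#'   name with `bands` giving passbands for envelope pre-filtering.
#' @param topography Unit-norm channel weight vector.
#' @param config From [simulation_config()].
#' @param trial_labels Character label per trial (selects the kernel).
#' @param bands Optional named list of passbands (Hz) when `kernels` is
#'   band-keyed.
#' @param onset_gain Amplitude of the type-independent auditory onset
#'   response added to every trial, as a multiple of the standard
#'   deviation of the envelope-driven component (default 2; onset-evoked
#'   transients in real recordings dominate the sustained envelope
#'   tracking, and the PCA spatial-filter step relies on them). Set 0 for
#'   purely kernel-driven data.
#' @param seed Seed for the noise (default `config$master_seed`).
#' @return An `eeg_epochs` object with `trial_meta$am_type`.
#' @export
simulate_eeg <- function(envelopes, kernels, topography, config,
                         trial_labels, bands = NULL, onset_gain = 2,
                         seed = config$master_seed) {
  snr_db <- config$response_snr_db
  if (is.null(snr_db) || is.na(snr_db) || snr_db == -Inf) {
    stop("response_snr_db must be a number or +Inf (noise off)")
  }
  fs <- config$fs
  n_trials <- length(envelopes)
  stopifnot(length(trial_labels) == n_trials)
  span <- config$epoch_span
  ns <- round((span[2] - span[1]) * fs)
  t0 <- -span[1]
  onset_i <- round(t0 * fs) + 1
  nch <- length(topography)
  band_keyed <- !is.null(bands)
  comp <- matrix(0, n_trials, ns)
  for (i in seq_len(n_trials)) {
    env <- as.numeric(envelopes[[i]])
    lab <- trial_labels[i]
    drive <- numeric(length(env))
    if (band_keyed) {
      for (bn in names(bands)) {
        fe <- bandpass_envelope(env, fs, bands[[bn]], order = 4)
        k <- kernels[[bn]][[lab]]$kernel
        drive <- drive + stats::convolve(fe, rev(k), type = "open")[seq_along(env)]
      }
    } else {
      k <- kernels[[lab]]$kernel
      drive <- stats::convolve(env, rev(k), type = "open")[seq_along(env)]
    }
    idx <- onset_i:(onset_i + length(drive) - 1)
    idx <- idx[idx <= ns]
    comp[i, idx] <- drive[seq_along(idx)]
  }
  driven <- onset_i:min(ns, onset_i + max(lengths(envelopes)) - 1)
  sig_var <- stats::var(as.numeric(comp[, driven]))
  if (onset_gain > 0) {
    onset_resp <- onset_response_shape(fs) * onset_gain * sqrt(sig_var)
    idx <- onset_i:(onset_i + length(onset_resp) - 1)
    comp[, idx] <- comp[, idx] + rep(onset_resp, each = n_trials)
  }
  target_noise_var <- sig_var / 10^(snr_db / 10)
  noise_seeds <- derive_seeds(seed, n_trials * nch)
  data <- array(0, dim = c(n_trials, nch, ns))
  # unit-norm topography: projected unit-variance channel noise has unit variance
  scale <- sqrt(target_noise_var)
  for (i in seq_len(n_trials)) {
    data[i, , ] <- outer(topography, comp[i, ])
    if (scale > 0) {
      for (j in seq_len(nch)) {
        data[i, j, ] <- data[i, j, ] +
          one_over_f_noise(ns, config$noise_exponent,
                           noise_seeds[(i - 1) * nch + j]) * scale
      }
    }
  }
  eeg_epochs(data, fs = fs, t0 = t0,
             trial_meta = data.frame(am_type = trial_labels,
                                     stringsAsFactors = FALSE))
}

#' Simulate yes/no tone-detection behavior
#'
#' A logistic observer: on tone-present trials the probability of
#' reporting a tone is `plogis((local SNR - threshold) / slope)` with the
#' local SNR read at the observer's integration window; on tone-absent
#' trials the yes-rate is a fixed false-alarm rate.
#'
#' @param snr_table Data frame with one row per stimulus: `id`, `am_type`,
#'   `tone_present` (logical), and `snr_db` (local SNR at the observer's
#'   integration window; NA on tone-absent trials).
#' @param config From [simulation_config()]; uses the psychometric fields.
#' @param n_participants Number of simulated participants (default 19).
#' @param seed Seed (default `config$master_seed`).
#' @return Trial-response data frame: `participant_id`, `stimulus_id`,
#'   `am_type`, `tone_present`, `reported_tone`.
#' @export
simulate_behavior <- function(snr_table, config, n_participants = 19,
                              seed = config$master_seed) {
  if (config$psychometric_slope_db <= 0) stop("psychometric slope must be > 0")
  stopifnot(all(c("id", "am_type", "tone_present", "snr_db") %in%
                  names(snr_table)))
  p_yes <- ifelse(snr_table$tone_present,
                  stats::plogis((snr_table$snr_db -
                                   config$psychometric_threshold_db) /
                                  config$psychometric_slope_db),
                  config$false_alarm_rate)
  n <- nrow(snr_table)
  draws <- with_seed(seed, stats::runif(n_participants * n))
  data.frame(
    participant_id = rep(sprintf("p%02d", seq_len(n_participants)), each = n),
    stimulus_id = rep(snr_table$id, n_participants),
    am_type = rep(snr_table$am_type, n_participants),
    tone_present = rep(snr_table$tone_present, n_participants),
    reported_tone = draws < rep(p_yes, n_participants),
    stringsAsFactors = FALSE)
}

#' Surrogate speech envelopes
#'
#' Synthetic stand-ins for broadband envelopes of 1-min connected-speech
#' segments: random-phase realizations of a modulation amplitude spectrum
#' `f^-1.5` with a Gaussian peak near 4 Hz (the syllabic rate), shifted to
#' be nonnegative. These emulate the spectral shape of real speech
#' envelopes, not their phase structure.
#'
#' @param n Number of segments (default 10).
#' @param duration Segment duration in s (default 60).
#' @param fs Sample rate in Hz (default 20000).
#' @param seed Integer seed.
#' @param peak_hz,peak_width,peak_gain Syllabic-peak parameters
#'   (defaults 4 Hz, 1.5 Hz, 3).
#' @return List of `n` nonnegative envelopes.
#' @export
surrogate_speech_envelopes <- function(n = 10, duration = 60, fs = 20000,
                                       seed = 1, peak_hz = 4,
                                       peak_width = 1.5, peak_gain = 3) {
  npts <- round(duration * fs)
  if (npts %% 2 == 1) npts <- npts + 1
  freqs <- (0:(npts / 2)) * fs / npts
  amp1 <- c(0, freqs[-1]^(-1.5)) *
    (1 + peak_gain * exp(-(freqs - peak_hz)^2 / (2 * peak_width^2)))
  seeds <- derive_seeds(seed, n)
  lapply(seq_len(n), function(i) {
    full <- numeric(npts)
    full[1:(npts / 2 + 1)] <- amp1
    full[(npts / 2 + 2):npts] <- rev(amp1[2:(npts / 2)])
    ph <- numeric(npts)
    pp <- with_seed(seeds[i], stats::runif(npts / 2 - 1, 0, 2 * pi))
    ph[2:(npts / 2)] <- pp
    ph[(npts / 2 + 2):npts] <- -rev(pp)
    x <- Re(stats::fft(full * exp(1i * ph), inverse = TRUE)) / npts
    x - min(x)
  })
}
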