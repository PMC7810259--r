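#' Resampled a-priori stimulus envelopes
#'
#' @param set A `stimulus_set`.
#' @param fs_out Target rate in Hz.
#' @return List of envelopes, one per stimulus, at `fs_out`.
#' @export
am_envelopes_at <- function(set, fs_out) {
  stopifnot(inherits(set, "stimulus_set"))
  lapply(set$stimuli, function(st) {
    resample_fft(st$envelope$samples,
                 round(length(st$envelope$samples) / st$envelope$fs * fs_out))
  })
}

#' Broadband cochlear envelopes for a stimulus set
#'
#' Streams each stimulus through the gammatone filterbank, keeping only
#' the broadband (band-mean Hilbert) envelope, optionally resampled.
#'
#' @param set A `stimulus_set` built with waveforms.
#' @param fs_out Optional output rate; the native rate if NULL.
#' @param bank Optional pre-built `gammatone_bank`.
#' @return List of broadband envelopes, one per stimulus.
#' @export
cochlear_broadband_set <- function(set, fs_out = NULL, bank = NULL) {
  stopifnot(inherits(set, "stimulus_set"))
  n <- length(set$stimuli[[1]]$waveform)
  if (is.null(bank)) {
    bank <- gammatone_bank(set$fs, nfft = next_pow2(n + round(0.1024 * set$fs)))
  }
  lapply(set$stimuli, function(st) {
    if (is.null(st$waveform)) stop("stimulus set was built without waveforms")
    bb <- cochlear_envelope(st$waveform, set$fs, bank = bank,
                            keep_bands = FALSE)$broadband
    if (is.null(fs_out)) bb else {
      resample_fft(bb, round(length(bb) / set$fs * fs_out))
    }
  })
}

#' Per-type modulation spectra and fitted exponents
#'
#' Estimates the mean modulation spectrum of each AM type, either from the
#' a-priori synthesized envelopes or from the gammatone broadband
#' envelopes of the stimuli, and fits the 1/f exponent over a frequency
#' range.
#'
#' @param set A `stimulus_set`.
#' @param source `"envelope"` (a-priori) or `"cochlear"` (gammatone).
#' @param f_lo,f_hi Exponent fit range in Hz (defaults 2 and 20).
#' @param bank Optional `gammatone_bank` (for `source = "cochlear"`).
#' @return Data frame with `am_type` and `exponent_fit`, plus the spectra
#'   in `attr(, "spectra")`.
#' @export
type_modulation_spectra <- function(set, source = c("envelope", "cochlear"),
                                    f_lo = 2, f_hi = 20, bank = NULL) {
  source <- match.arg(source)
  stopifnot(inherits(set, "stimulus_set"))
  envs <- if (source == "envelope") {
    lapply(set$stimuli, function(st) st$envelope$samples)
  } else {
    cochlear_broadband_set(set, bank = bank)
  }
  types <- set$am_types
  spectra <- list()
  fits <- numeric(length(types))
  for (i in seq_along(types)) {
    idx <- which(set$manifest$am_type == types[i])
    spectra[[types[i]]] <- modulation_spectrum_estimate(envs[idx], set$fs)
    fits[i] <- fit_exponent(spectra[[types[i]]], f_lo, f_hi)
  }
  out <- data.frame(am_type = types, exponent_fit = fits,
                    stringsAsFactors = FALSE)
  attr(out, "spectra") <- spectra
  out
}

#' Local-SNR table for all probed stimuli of a set
#'
#' @param set A `stimulus_set` with waveforms.
#' @param window_sizes Window sizes in ms.
#' @return Long data frame: `stimulus_id`, `am_type`, `window_ms`,
#'   `snr_db`.
#' @export
local_snr_table <- function(set,
                            window_sizes = c(30, 50, 70, 100, 150, 200,
                                             250, 350, 500)) {
  stopifnot(inherits(set, "stimulus_set"))
  probed <- which(!is.na(set$manifest$probe_onset_s))
  do.call(rbind, lapply(probed, function(i) {
    p <- local_snr(set$stimuli[[i]], window_sizes = window_sizes)
    data.frame(stimulus_id = set$manifest$id[i],
               am_type = set$manifest$am_type[i],
               window_ms = p$window_ms, snr_db = p$snr_db,
               stringsAsFactors = FALSE)
  }))
}

#' Type-by-window matrix of mean local SNR
#'
#' @param snr_table Output of [local_snr_table()].
#' @return Matrix AM types x window sizes (colnames are window ms).
#' @export
type_window_snr <- function(snr_table) {
  types <- unique(snr_table$am_type)
  windows <- sort(unique(snr_table$window_ms))
  out <- matrix(NA_real_, length(types), length(windows),
                dimnames = list(types, windows))
  for (ty in types) {
    for (w in windows) {
      sel <- snr_table$am_type == ty & snr_table$window_ms == w
      out[ty, as.character(w)] <- mean(snr_table$snr_db[sel])
    }
  }
  out
}

#' Simulate a full EEG session for a stimulus set
#'
#' Convenience wrapper: builds ground-truth kernels and topography,
#' resamples the stimulus envelopes to the EEG rate, and simulates
#' multi-channel epochs.
#'
#' @param set A `stimulus_set`.
#' @param config From [simulation_config()].
#' @param mode Kernel mode (`"specific"` or `"shared"`).
#' @param seed Noise seed (default `config$master_seed`).
#' @param onset_gain Passed to [simulate_eeg()].
#' @return List with `epochs`, `kernels`, `topography`, `envelopes`
#'   (at the EEG rate) and `labels`.
#' @export
simulate_session <- function(set, config, mode = "specific",
                             seed = config$master_seed, onset_gain = 2) {
  stopifnot(inherits(set, "stimulus_set"))
  envelopes <- am_envelopes_at(set, config$fs)
  kernels <- make_kernels(set$am_types, fs = config$fs, mode = mode)
  topography <- make_topography(config$n_channels)
  epochs <- simulate_eeg(envelopes, kernels, topography, config,
                         trial_labels = set$manifest$am_type,
                         onset_gain = onset_gain, seed = seed)
  list(epochs = epochs, kernels = kernels, topography = topography,
       envelopes = envelopes, labels = set$manifest$am_type)
}

#' Slice per-trial responses at the TRF working rate
#'
#' Resamples each trial of a component signal to `fs_work` and extracts
#' the stimulus window (onset to onset + duration).
#'
#' @param component A `component_signal`.
#' @param fs_work Working rate in Hz (default 128).
#' @param duration Stimulus duration in s (default 5).
#' @return List of per-trial response vectors.
#' @export
component_responses <- function(component, fs_work = 128, duration = 5) {
  stopifnot(inherits(component, "component_signal"))
  ns <- ncol(component$data)
  n_new <- round(ns / component$fs * fs_work)
  i0 <- round(component$t0 * fs_work) + 1
  len <- round(duration * fs_work)
  lapply(seq_len(nrow(component$data)), function(i) {
    resample_fft(component$data[i, ], n_new)[i0:(i0 + len - 1)]
  })
}

#' End-to-end TRF recovery analysis on simulated EEG
#'
#' Runs the standard analysis chain on a simulated session (preprocess,
#' PCA spatial filter, projection, per-type cross-validated TRF) and
#' compares the estimated kernels and topography with the ground truth.
#'
#' @param set A `stimulus_set` (envelopes are used as the regressor).
#' @param session Output of [simulate_session()].
#' @param fs_work TRF working rate in Hz (default 128).
#' @param drop_initial_s Onset window excluded from fitting (default 0.5).
#' @param lambda_grid Ridge grid.
#' @param regressor_band Passband applied to the envelope regressor with
#'   the same zero-phase FIR used on the EEG (default `c(1, 45)` Hz; an
#'   unmatched regressor carries sub-1-Hz content the filtered response
#'   cannot contain, which biases the kernel estimate).
#' @return List with `topography_cos`, per-type `recovery` (correlation of
#'   estimated vs true kernel), `fits`, and the `component` signal.
#' @export
trf_recovery_analysis <- function(set, session, fs_work = 128,
                                  drop_initial_s = 0.5,
                                  lambda_grid = default_lambda_grid(),
                                  regressor_band = c(1, 45)) {
  epochs <- preprocess_eeg(session$epochs)
  filt <- fit_spatial_filter(epochs)
  comp <- apply_spatial_filter(epochs, filt)
  rm(epochs)
  resp <- component_responses(comp, fs_work)
  fs_env <- comp$fs
  n_out <- round(length(session$envelopes[[1]]) / fs_env * fs_work)
  envs <- lapply(session$envelopes, function(e) {
    resample_fft(fir_bandpass(e, fs_env, regressor_band), n_out)
  })
  types <- set$am_types
  fits <- list()
  recovery <- numeric(length(types))
  names(recovery) <- types
  for (ty in types) {
    idx <- which(session$labels == ty)
    fits[[ty]] <- train_with_cv(envs[idx], resp[idx], fs_work,
                                lambda_grid = lambda_grid,
                                drop_initial_s = drop_initial_s)
    ktrue <- resample_fft(session$kernels[[ty]]$kernel,
                          length(fits[[ty]]$model$kernel))
    recovery[ty] <- stats::cor(fits[[ty]]$model$kernel, ktrue)
  }
  list(topography_cos = abs(sum(filt$weights * session$topography)),
       recovery = recovery, fits = fits, spatial_filter = filt,
       component = comp)
}
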