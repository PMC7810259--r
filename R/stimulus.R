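#' Construct a target modulation spectrum
#'
#' Builds the a-priori modulation amplitude spectrum used for inverse-FFT
#' envelope synthesis: either a 1/f shape with a given exponent (amplitude
#' proportional to `f^-exponent`; the exponent applies to the amplitude, not
#' the power, spectrum) or an empirical speech-derived shape obtained by
#' averaging the FFT magnitude spectra of supplied broadband envelopes and
#' resampling onto the synthesis grid.
#'
#' The DC bin is set to 0 (the mean level is re-imposed later by depth
#' normalization, and a 1/f amplitude diverges at f = 0).
#'
#' @param kind `"one_over_f"` or `"speech_derived"`.
#' @param exponent Nonnegative 1/f exponent (required for `one_over_f`).
#' @param reference_envelopes List of numeric envelopes at rate `fs`
#'   (required for `speech_derived`).
#' @param n_points Number of time-domain points the spectrum maps onto
#'   (default `fs * 10`, a 10-s synthesis grid).
#' @param fs Sample rate in Hz (default 20000).
#' @return A `modulation_spectrum` object with one-sided `frequencies`
#'   and `amplitudes` (length `n_points/2 + 1`).
#' @export
make_modulation_spectrum <- function(kind = c("one_over_f", "speech_derived"),
                                     exponent = NULL,
                                     reference_envelopes = NULL,
                                     n_points = fs * 10, fs = 20000) {
  kind <- match.arg(kind)
  stopifnot(n_points %% 2 == 0, n_points > 4)
  freqs <- (0:(n_points / 2)) * fs / n_points
  if (kind == "one_over_f") {
    if (is.null(exponent) || exponent < 0) {
      stop("one_over_f spectrum requires a nonnegative exponent")
    }
    amps <- c(0, freqs[-1]^(-exponent))
  } else {
    if (is.null(reference_envelopes) || length(reference_envelopes) == 0) {
      stop("speech_derived spectrum requires at least one reference envelope")
    }
    specs <- lapply(reference_envelopes, function(e) {
      m <- magnitude_spectrum(as.numeric(e), fs, taper = "none")
      m$amplitudes <- m$amplitudes / length(e)  # per-sample scale
      m
    })
    mean_amp <- Reduce(`+`, lapply(specs, `[[`, "amplitudes")) / length(specs)
    amps <- stats::approx(specs[[1]]$frequencies, mean_amp, xout = freqs,
                          rule = 2)$y
    amps[1] <- 0
  }
  structure(list(frequencies = freqs, amplitudes = amps, kind = kind,
                 exponent = if (kind == "one_over_f") exponent else NULL,
                 n_points = n_points, fs = fs),
            class = "modulation_spectrum")
}

#' Synthesize an amplitude-modulation envelope from a target spectrum
#'
#' Inverse-FFT synthesis: the one-sided amplitude spectrum is combined with
#' phases drawn uniformly on `[0, 2*pi)` (conjugate-symmetrized so the time
#' series is real), transformed to the time domain, conditioned with a
#' forward high-pass Butterworth (order 3, 1 Hz) and low-pass Butterworth
#' (order 6, 30 Hz), trimmed to its middle half (discarding filter edge
#' artifacts), and normalized to 100% modulation depth so that
#' `min == 0` and `max == 1` exactly.
#'
#' @param spectrum A `modulation_spectrum`.
#' @param seed Integer seed for the random phases.
#' @param hp_hz,hp_order High-pass corner and order (defaults 1 Hz, 3).
#' @param lp_hz,lp_order Low-pass corner and order (defaults 30 Hz, 6).
#' @return An `am_envelope`: `samples` (length `n_points / 2`), `fs`,
#'   `duration`, `depth = 1`, `seed`, and a summary of the source spectrum.
#' @export
synthesize_envelope <- function(spectrum, seed,
                                hp_hz = 1, hp_order = 3,
                                lp_hz = 30, lp_order = 6) {
  stopifnot(inherits(spectrum, "modulation_spectrum"))
  n <- spectrum$n_points
  fs <- spectrum$fs
  if (length(spectrum$amplitudes) != n / 2 + 1) {
    stop("spectrum amplitudes do not match its n_points grid")
  }
  amp <- numeric(n)
  amp[1:(n / 2 + 1)] <- spectrum$amplitudes
  amp[(n / 2 + 2):n] <- rev(spectrum$amplitudes[2:(n / 2)])
  ph <- numeric(n)
  pos_ph <- with_seed(seed, stats::runif(n / 2 - 1, 0, 2 * pi))
  ph[2:(n / 2)] <- pos_ph
  ph[(n / 2 + 2):n] <- -rev(pos_ph)
  x <- Re(stats::fft(amp * exp(1i * ph), inverse = TRUE)) / n
  hp <- signal::butter(hp_order, hp_hz / (fs / 2), type = "high")
  lp <- signal::butter(lp_order, lp_hz / (fs / 2), type = "low")
  x <- as.numeric(signal::filter(lp, as.numeric(signal::filter(hp, x))))
  mid <- x[(n / 4 + 1):(3 * n / 4)]
  samples <- (mid - min(mid)) / (max(mid) - min(mid))
  structure(list(samples = samples, fs = fs, duration = length(samples) / fs,
                 depth = 1, seed = seed,
                 source_spectrum = list(kind = spectrum$kind,
                                        exponent = spectrum$exponent)),
            class = "am_envelope")
}

raised_cosine_ramps <- function(n, fs, ramp_s) {
  nr <- round(ramp_s * fs)
  w <- rep(1, n)
  if (nr > 0) {
    edge <- sin(pi * (0:(nr - 1)) / (2 * nr))^2  # 0 at the first sample
    w[1:nr] <- edge
    w[(n - nr + 1):n] <- rev(edge)
  }
  w
}

#' Modulate white noise with an AM envelope
#'
#' Multiplies a fresh standard-normal white-noise carrier by the envelope,
#' applies 50-ms raised-cosine onset/offset ramps, and scales the result to
#' a target RMS (a digital stand-in for presentation-level calibration).
#'
#' @param envelope An `am_envelope`.
#' @param noise_seed Integer seed for the carrier.
#' @param target_rms Target root-mean-square amplitude (default 0.05).
#' @param ramp_s Ramp duration in seconds (default 0.05).
#' @param am_type Optional label stored with the stimulus.
#' @return An `am_stimulus` with `waveform`, `fs`, `am_type`, `envelope`,
#'   `probe` (absent), `noise_seed`, and `rms`.
#' @export
modulate_noise <- function(envelope, noise_seed, target_rms = 0.05,
                           ramp_s = 0.05, am_type = NA_character_) {
  stopifnot(inherits(envelope, "am_envelope"))
  n <- length(envelope$samples)
  carrier <- with_seed(noise_seed, stats::rnorm(n))
  w <- carrier * envelope$samples
  w <- w * raised_cosine_ramps(n, envelope$fs, ramp_s)
  r <- sqrt(mean(w^2))
  if (r > 0) w <- w * (target_rms / r)
  structure(list(waveform = w, fs = envelope$fs, am_type = am_type,
                 envelope = envelope, probe = NULL, noise_seed = noise_seed,
                 rms = sqrt(mean(w^2))),
            class = "am_stimulus")
}

#' Waveform of a ramped probe tone
#'
#' @param probe Probe descriptor (list with `frequency`, `duration`,
#'   `ramp`, `scale`).
#' @param fs Sample rate in Hz.
#' @return Numeric vector of `round(duration * fs)` samples.
#' @export
probe_waveform <- function(probe, fs) {
  n <- round(probe$duration * fs)
  t <- (0:(n - 1)) / fs
  tone <- sin(2 * pi * probe$frequency * t)
  nr <- round(probe$ramp * fs)
  if (nr > 0) {
    tone[1:nr] <- tone[1:nr] * sin(pi * (0:(nr - 1)) / (2 * nr))^2
    tone[(n - nr + 1):n] <- tone[(n - nr + 1):n] * rev(sin(pi * (0:(nr - 1)) / (2 * nr))^2)
  }
  tone * probe$scale
}

#' Insert a probe tone into an AM stimulus at a fixed global SNR
#'
#' Adds (sums onto the masker) a 1000-Hz, 30-ms tone with 10-ms ramps at an
#' onset drawn uniformly from `[0.75, 4.25]` s. The tone is scaled so that
#' its mean-square power over its own duration, divided by the long-term
#' mean-square power of the full 5-s AM waveform (probe excluded), equals
#' `10^(snr_db / 10)`; with the default `-10` dB the global SNR is the same
#' for every stimulus regardless of where the tone lands.
#'
#' @param stimulus An `am_stimulus` without a probe.
#' @param probe_seed Integer seed for the onset draw.
#' @param frequency Tone frequency in Hz (default 1000).
#' @param duration Tone duration in s (default 0.030).
#' @param snr_db Global tone-to-masker SNR in dB (default -10).
#' @param onset_range Allowed onset interval in s (default `c(0.75, 4.25)`).
#' @param ramp Tone ramp duration in s (default 0.010).
#' @return The stimulus with the tone added and `probe` metadata set.
#' @export
insert_tone <- function(stimulus, probe_seed, frequency = 1000,
                        duration = 0.030, snr_db = -10,
                        onset_range = c(0.75, 4.25), ramp = 0.010) {
  stopifnot(inherits(stimulus, "am_stimulus"))
  if (!is.null(stimulus$probe)) stop("stimulus already carries a probe tone")
  fs <- stimulus$fs
  onset <- with_seed(probe_seed, stats::runif(1, onset_range[1], onset_range[2]))
  onset <- round(onset * fs) / fs
  probe <- list(frequency = frequency, duration = duration, onset = onset,
                snr_db = snr_db, ramp = ramp, scale = 1)
  unit <- probe_waveform(probe, fs)
  masker_ms <- mean(stimulus$waveform^2)
  target_ms <- 10^(snr_db / 10) * masker_ms
  probe$scale <- sqrt(target_ms / mean(unit^2))
  tone <- probe_waveform(probe, fs)
  i0 <- round(onset * fs) + 1
  idx <- i0:(i0 + length(tone) - 1)
  if (max(idx) > length(stimulus$waveform)) stop("probe extends past stimulus end")
  stimulus$waveform[idx] <- stimulus$waveform[idx] + tone
  stimulus$probe <- probe
  stimulus
}

#' Build the full AM stimulus set
#'
#' Generates `n_per_type` stimuli for each AM type (five 1/f exponents and
#' one speech-derived modulation spectrum by default), embeds a probe tone
#' in a random half of each type, and records a manifest. The whole set is
#' a pure function of `(config, master_seed)`.
#'
#' @param master_seed Integer master seed.
#' @param exponents 1/f exponents (default `c(0.5, 0.75, 1, 1.5, 2)`).
#' @param include_speech Include the speech-derived type (default TRUE);
#'   its reference envelopes are surrogate speech envelopes generated by
#'   [surrogate_speech_envelopes()] unless supplied.
#' @param speech_reference Optional list of broadband envelopes at `fs`
#'   from which the speech modulation spectrum is derived.
#' @param n_per_type Stimuli per type (default 60).
#' @param fs Sample rate in Hz (default 20000).
#' @param target_rms Target stimulus RMS (default 0.05).
#' @param probe Probe settings: list with `frequency`, `duration`, `snr_db`,
#'   `onset_range`, `ramp`.
#' @param keep_waveforms Keep waveforms in memory (default TRUE); with
#'   FALSE only envelopes and the manifest are kept.
#' @return A `stimulus_set`: list of `am_stimulus` objects, a `manifest`
#'   data frame (id, am_type, envelope_seed, noise_seed, probe_onset_s,
#'   snr_db), and the spectra used.
#' @export
build_stimulus_set <- function(master_seed,
                               exponents = c(0.5, 0.75, 1, 1.5, 2),
                               include_speech = TRUE,
                               speech_reference = NULL,
                               n_per_type = 60, fs = 20000,
                               target_rms = 0.05,
                               probe = list(frequency = 1000, duration = 0.030,
                                            snr_db = -10,
                                            onset_range = c(0.75, 4.25),
                                            ramp = 0.010),
                               keep_waveforms = TRUE) {
  types <- paste0("e", sub("\\.?0+$", "", formatC(exponents, format = "f", digits = 2)))
  if (include_speech) types <- c(types, "speech")
  n_types <- length(types)
  seeds <- derive_seeds(master_seed, 3 * n_types * n_per_type + 2)
  env_seeds <- matrix(seeds[1:(n_types * n_per_type)], n_per_type, n_types)
  noise_seeds <- matrix(seeds[(n_types * n_per_type + 1):(2 * n_types * n_per_type)],
                        n_per_type, n_types)
  probe_seeds <- matrix(seeds[(2 * n_types * n_per_type + 1):(3 * n_types * n_per_type)],
                        n_per_type, n_types)
  pick_seed <- seeds[3 * n_types * n_per_type + 1]
  speech_seed <- seeds[3 * n_types * n_per_type + 2]
  if (any(duplicated(c(env_seeds)))) stop("duplicate envelope seeds drawn")

  spectra <- list()
  for (i in seq_along(exponents)) {
    spectra[[types[i]]] <- make_modulation_spectrum("one_over_f",
                                                    exponent = exponents[i],
                                                    fs = fs)
  }
  if (include_speech) {
    if (is.null(speech_reference)) {
      speech_reference <- surrogate_speech_envelopes(seed = speech_seed, fs = fs)
    }
    spectra[["speech"]] <- make_modulation_spectrum("speech_derived",
                                                    reference_envelopes = speech_reference,
                                                    fs = fs)
  }

  stimuli <- vector("list", n_types * n_per_type)
  manifest <- data.frame()
  probed <- with_seed(pick_seed, {
    lapply(seq_len(n_types), function(i) sort(sample.int(n_per_type, n_per_type %/% 2)))
  })
  k <- 0
  for (i in seq_len(n_types)) {
    for (j in seq_len(n_per_type)) {
      k <- k + 1
      env <- synthesize_envelope(spectra[[types[i]]], seed = env_seeds[j, i])
      st <- modulate_noise(env, noise_seed = noise_seeds[j, i],
                           target_rms = target_rms, am_type = types[i])
      has_probe <- j %in% probed[[i]]
      if (has_probe) {
        st <- insert_tone(st, probe_seed = probe_seeds[j, i],
                          frequency = probe$frequency, duration = probe$duration,
                          snr_db = probe$snr_db, onset_range = probe$onset_range,
                          ramp = probe$ramp)
      }
      st$id <- sprintf("%s_%02d_%s", types[i], j, if (has_probe) "tone" else "notone")
      if (!keep_waveforms) st$waveform <- NULL
      stimuli[[k]] <- st
      manifest <- rbind(manifest, data.frame(
        id = st$id, am_type = types[i],
        envelope_seed = env_seeds[j, i], noise_seed = noise_seeds[j, i],
        probe_onset_s = if (has_probe) st$probe$onset else NA_real_,
        snr_db = if (has_probe) probe$snr_db else NA_real_,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(stimuli = stimuli, manifest = manifest, spectra = spectra,
                 am_types = types, fs = fs, master_seed = master_seed),
            class = "stimulus_set")
}

#' Subset a stimulus set by stimulus index
#'
#' @param set A `stimulus_set`.
#' @param idx Integer indices into the stimuli/manifest.
#' @return The reduced `stimulus_set`.
#' @export
subset_stimuli <- function(set, idx) {
  stopifnot(inherits(set, "stimulus_set"))
  set$stimuli <- set$stimuli[idx]
  set$manifest <- set$manifest[idx, , drop = FALSE]
  rownames(set$manifest) <- NULL
  set$am_types <- intersect(set$am_types, unique(set$manifest$am_type))
  set
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("AM stimulus set:", length(x$stimuli), "stimuli,",
      length(x$am_types), "types (", paste(x$am_types, collapse = ", "), ")\n")
  cat("probed:", sum(!is.na(x$manifest$probe_onset_s)), "of",
      nrow(x$manifest), "\n")
  invisible(x)
}

#' Write a stimulus set to WAV files plus a manifest
#'
#' Writes one 32-bit float mono RIFF/WAV file per stimulus and a
#' tab-separated manifest.
#'
#' @param set A `stimulus_set` with waveforms.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_stimulus_set <- function(set, dir) {
  stopifnot(inherits(set, "stimulus_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (st in set$stimuli) {
    if (is.null(st$waveform)) stop("stimulus set was built without waveforms")
    write_wav_float(st$waveform, st$fs, file.path(dir, paste0(st$id, ".wav")))
  }
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(set$manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a mono 32-bit float WAV file
#' @param x Numeric waveform in [-1, 1] (not checked).
#' @param fs Sample rate in Hz.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_wav_float <- function(x, fs, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  data_bytes <- 4L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")   # IEEE float
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 4L), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(x, con, size = 4, endian = "little")
  invisible(path)
}
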