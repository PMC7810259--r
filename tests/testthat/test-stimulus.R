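test_that("1/f modulation spectra follow the amplitude power law", {
  flat <- make_modulation_spectrum("one_over_f", exponent = 0)
  expect_true(all(abs(flat$amplitudes[-1] - 1) < 1e-12))
  expect_identical(flat$amplitudes[1], 0)

  sp <- make_modulation_spectrum("one_over_f", exponent = 1)
  a2 <- sp$amplitudes[which.min(abs(sp$frequencies - 2))]
  a4 <- sp$amplitudes[which.min(abs(sp$frequencies - 4))]
  expect_equal(a2 / a4, 2, tolerance = 1e-9)

  expect_error(make_modulation_spectrum("one_over_f", exponent = -1),
               "nonnegative")
  expect_error(make_modulation_spectrum("speech_derived",
                                        reference_envelopes = list()),
               "reference")
})

test_that("speech-derived spectrum equals the mean of reference spectra", {
  fs <- 2000
  n <- fs * 2
  refs <- lapply(1:5, function(i) with_seed(i, abs(stats::rnorm(n))))
  sp <- make_modulation_spectrum("speech_derived", reference_envelopes = refs,
                                 n_points = n, fs = fs)
  # direct averaging oracle on the same grid
  oracle <- Reduce(`+`, lapply(refs, function(e) {
    Mod(stats::fft(e))[1:(n / 2 + 1)] / n
  })) / length(refs)
  oracle[1] <- 0
  expect_equal(sp$amplitudes, oracle, tolerance = 1e-10)
})

test_that("synthesized envelopes are deterministic with exact 100% depth", {
  sp <- make_modulation_spectrum("one_over_f", exponent = 1)
  e1 <- synthesize_envelope(sp, seed = 42)
  e2 <- synthesize_envelope(sp, seed = 42)
  expect_identical(e1$samples, e2$samples)
  expect_false(identical(e1$samples,
                         synthesize_envelope(sp, seed = 43)$samples))
  expect_identical(min(e1$samples), 0)
  expect_identical(max(e1$samples), 1)
  expect_equal(e1$duration * e1$fs, length(e1$samples))

  bad <- sp
  bad$amplitudes <- bad$amplitudes[-1]
  expect_error(synthesize_envelope(bad, seed = 1), "grid")
})

test_that("mean envelope spectra recover the generating exponent", {
  for (chi in c(0.5, 2)) {
    sp <- make_modulation_spectrum("one_over_f", exponent = chi)
    envs <- lapply(1:60, function(s) synthesize_envelope(sp, seed = s)$samples)
    est <- modulation_spectrum_estimate(envs, fs = 20000)
    expect_lt(abs(fit_exponent(est, 2, 20) - chi), 0.1)
  }
})

test_that("noise modulation ramps, scales and silences correctly", {
  sp <- make_modulation_spectrum("one_over_f", exponent = 1)
  env <- synthesize_envelope(sp, seed = 5)

  flat <- env
  flat$samples <- rep(1, length(env$samples))
  st <- modulate_noise(flat, noise_seed = 9, target_rms = 0.05)
  expect_equal(st$rms, 0.05, tolerance = 1e-12)
  expect_identical(st$waveform[1], 0)
  expect_identical(st$waveform[length(st$waveform)], 0)
  # raised-cosine ramp is monotone over the first and last 50 ms
  w <- raised_cosine_ramps(length(st$waveform), st$fs, 0.05)
  nr <- round(0.05 * st$fs)
  expect_true(all(diff(w[1:nr]) >= 0))
  expect_true(all(diff(w[(length(w) - nr + 1):length(w)]) <= 0))

  silent <- env
  silent$samples <- rep(0, length(env$samples))
  expect_identical(max(abs(modulate_noise(silent, 9)$waveform)), 0)
})

test_that("modulated noise carries the envelope (demodulation oracle)", {
  sp <- make_modulation_spectrum("one_over_f", exponent = 1)
  env <- synthesize_envelope(sp, seed = 21)
  st <- modulate_noise(env, noise_seed = 22)
  demod <- Mod(analytic_signal(st$waveform))
  band <- function(x) bandpass_envelope(x, st$fs, c(2, 20), order = 2)
  expect_gt(stats::cor(band(demod), band(env$samples)), 0.95)
})

test_that("probe tones hit the -10 dB global SNR convention", {
  pair <- probed_pair()
  st <- pair$probed
  tone <- probe_waveform(st$probe, st$fs)
  snr <- 10 * log10(mean(tone^2) / mean(pair$clean$waveform^2))
  expect_equal(snr, -10, tolerance = 0.01)
  expect_error(insert_tone(st, probe_seed = 1), "already")

  # equal-power case: masker RMS 1 and snr 0 dB gives tone RMS 1
  unit <- pair$clean
  unit$waveform <- unit$waveform / sqrt(mean(unit$waveform^2))
  st0 <- insert_tone(unit, probe_seed = 2, snr_db = 0)
  tone0 <- probe_waveform(st0$probe, st0$fs)
  expect_equal(sqrt(mean(tone0^2)), 1, tolerance = 1e-9)
})

test_that("probe onsets stay inside the allowed window", {
  # Monte-Carlo bounds on the onset draw used by insert_tone
  onsets <- vapply(seq_len(10000), function(s) {
    with_seed(s, stats::runif(1, 0.75, 4.25))
  }, numeric(1))
  expect_gte(min(onsets), 0.75)
  expect_lte(max(onsets), 4.25)
  pair <- probed_pair()
  for (s in 1:20) {
    st <- insert_tone(pair$clean, probe_seed = s)
    expect_true(st$probe$onset >= 0.75 && st$probe$onset <= 4.25)
    expect_lte(st$probe$onset + st$probe$duration, 5)
  }
})

test_that("stimulus sets are complete, half-probed and reproducible", {
  set <- mini_set()
  expect_s3_class(set, "stimulus_set")
  expect_length(set$stimuli, 3 * 6)
  counts <- table(set$manifest$am_type)
  expect_true(all(counts == 6))
  probed <- tapply(!is.na(set$manifest$probe_onset_s), set$manifest$am_type,
                   sum)
  expect_true(all(probed == 3))
  expect_false(any(duplicated(set$manifest$envelope_seed)))

  set2 <- build_stimulus_set(master_seed = 404, exponents = c(0.5, 2),
                             include_speech = TRUE, n_per_type = 6)
  expect_identical(set$manifest, set2$manifest)
  expect_identical(set$stimuli[[4]]$waveform, set2$stimuli[[4]]$waveform)
})

test_that("WAV output round-trips header and samples", {
  path <- tempfile(fileext = ".wav")
  x <- sin(2 * pi * 440 * (0:999) / 20000)
  write_wav_float(x, 20000, path)
  con <- file(path, "rb")
  hdr <- readBin(con, "raw", 44)
  expect_identical(rawToChar(hdr[1:4]), "RIFF")
  expect_identical(rawToChar(hdr[9:12]), "WAVE")
  back <- readBin(con, "double", n = 1000, size = 4)
  close(con)
  expect_equal(back, x, tolerance = 1e-6)
})
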