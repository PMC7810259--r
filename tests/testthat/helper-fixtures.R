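# shared fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

# small stimulus set: 2 exponents + speech surrogate, 6 stimuli per type
mini_set <- function() {
  if (is.null(.fixtures$mini_set)) {
    .fixtures$mini_set <- build_stimulus_set(
      master_seed = 404, exponents = c(0.5, 2), include_speech = TRUE,
      n_per_type = 6)
  }
  .fixtures$mini_set
}

# one probed and one unprobed stimulus sharing the same masker
probed_pair <- function() {
  if (is.null(.fixtures$probed_pair)) {
    sp <- make_modulation_spectrum("one_over_f", exponent = 1)
    env <- synthesize_envelope(sp, seed = 11)
    clean <- modulate_noise(env, noise_seed = 12, am_type = "e1")
    .fixtures$probed_pair <- list(clean = clean,
                                  probed = insert_tone(clean, probe_seed = 13))
  }
  .fixtures$probed_pair
}

# deterministic sinusoidal "masker" with a manually scaled probe
sine_masker <- function(fs = 20000, dur = 5, freq = 300) {
  sin(2 * pi * freq * (0:(dur * fs - 1)) / fs)
}
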