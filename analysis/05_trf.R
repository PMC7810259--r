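#!/usr/bin/env Rscript
# Step 5: ridge TRF estimation, kernel recovery and cross-encoding.
#
# Continues from the simulated session of step 4: estimates one TRF per
# AM type (leave-one-out lambda selection on 50 trials, 0-500 ms lags at
# 128 Hz, onset window excluded) and compares the kernels with the ground
# truth. Then builds the six-by-six cross-encoding matrix at the
# operation level for a small group of simulated participants and derives
# per-cell permutation thresholds (mean-summary scheme).

library(modtrf)

dir.create("results", showWarnings = FALSE)
set <- build_stimulus_set(master_seed = 1, n_per_type = 50,
                          keep_waveforms = FALSE)
cfg <- simulation_config(epoch_span = c(-1.5, 6.5), master_seed = 1)
sess <- simulate_session(set, cfg, mode = "specific", seed = 2)
message("recovering TRFs from the simulated session ...")
rec <- trf_recovery_analysis(set, sess)
summary_tab <- data.frame(
  am_type = set$am_types,
  lambda = vapply(rec$fits, `[[`, numeric(1), "lambda"),
  heldout_z = vapply(rec$fits, `[[`, numeric(1), "z"),
  kernel_recovery_r = as.numeric(rec$recovery))
print(summary_tab, digits = 3)
write.csv(summary_tab, "results/trf_recovery.csv", row.names = FALSE)

kernels <- data.frame(lag_ms = rec$fits[[1]]$model$lags_ms)
for (ty in set$am_types) kernels[[ty]] <- round(rec$fits[[ty]]$model$kernel, 6)
write.csv(kernels, "results/trf_kernels.csv", row.names = FALSE)

message("cross-encoding for 5 simulated participants (operation level) ...")
envs128 <- lapply(am_envelopes_at(set, 128), function(e) e[1:640])
labels <- set$manifest$am_type
ks <- make_kernels(set$am_types, fs = 500, mode = "specific")
pseeds <- derive_seeds(21, 5)
zmat <- array(NA_real_, c(5, length(set$am_types), length(set$am_types)),
              dimnames = list(NULL, set$am_types, set$am_types))
for (p in 1:5) {
  nseeds <- derive_seeds(pseeds[p], length(envs128))
  trials <- list()
  for (ty in set$am_types) {
    idx <- which(labels == ty)
    kk <- resample_fft(ks[[ty]]$kernel, 65)
    trials[[ty]] <- list(
      envelopes = envs128[idx],
      responses = lapply(idx, function(i) {
        X <- lagged_design(scale(envs128[[i]])[, 1], 128)
        y <- drop(X %*% c(0, kk))
        y + with_seed(nseeds[i], stats::rnorm(length(y), 0, sd(y)))
      }))
  }
  zmat[p, , ] <- cross_encode(trials, fs = 128)$values
}
group_mean <- apply(zmat, c(2, 3), mean)
message("group-mean cross-encoding matrix (train x test, Fisher z):")
print(round(group_mean, 3))
write.csv(round(group_mean, 4), "results/cross_encoding_matrix.csv")

flat <- matrix(zmat, 5, length(set$am_types)^2)
colnames(flat) <- as.vector(outer(set$am_types, set$am_types,
                                  function(a, b) paste(a, b, sep = "->")))
pn <- permutation_threshold(flat, "mean_summary", n_perm = 1000,
                            alphas = c(0.05, 0.01), seed = 22)
sig <- matrix(pn$flagged["alpha_0.01", ], length(set$am_types),
              dimnames = dimnames(group_mean))
message("cells exceeding the one-sided alpha = 0.01 permutation threshold:")
print(sig)

diag_margin <- min(diag(group_mean) -
                     rowMeans(group_mean - diag(diag(group_mean))) *
                     length(set$am_types) / (length(set$am_types) - 1))
message(sprintf(
  "findings: kernel recovery r = %.2f-%.2f; every diagonal cell exceeds its row's off-diagonal mean (min margin %.2f z), i.e. the TRFs are specific to their modulation spectrum",
  min(summary_tab$kernel_recovery_r), max(summary_tab$kernel_recovery_r),
  diag_margin))
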