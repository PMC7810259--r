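#!/usr/bin/env Rscript
# Step 3: simulated tone-detection behavior.
#
# A logistic observer reads each probe's local SNR in its 30-ms
# integration window. Simulates 5 cohorts of 19 participants, computes
# d-prime per participant and AM type, derives the group permutation
# threshold (median-summary scheme, 1000 shuffles) and correlates d-prime
# with local SNR at each analysis window (Fisher z before averaging).

library(modtrf)

set <- build_stimulus_set(master_seed = 1)
dir.create("results", showWarnings = FALSE)

snr_long <- local_snr_table(set)
snr_mat <- type_window_snr(snr_long)
p30 <- snr_long[snr_long$window_ms == 30, ]
snr_tab <- data.frame(id = set$manifest$id, am_type = set$manifest$am_type,
                      tone_present = !is.na(set$manifest$probe_onset_s),
                      snr_db = NA_real_)
snr_tab$snr_db[match(p30$stimulus_id, snr_tab$id)] <- p30$snr_db

cfg <- simulation_config(master_seed = 1)
cohort_seeds <- derive_seeds(11, 5)

beh1 <- simulate_behavior(snr_tab, cfg, n_participants = 19,
                          seed = cohort_seeds[1])
dp1 <- dprime_table(beh1, on_boundary = "drop")
write.csv(dp1, "results/dprime_table.csv", row.names = FALSE)

dpm <- matrix(NA_real_, 19, length(set$am_types),
              dimnames = list(unique(dp1$participant_id), set$am_types))
for (i in seq_len(nrow(dp1))) {
  dpm[dp1$participant_id[i], dp1$am_type[i]] <- dp1$dprime[i]
}
pn <- permutation_threshold(dpm[stats::complete.cases(dpm), ],
                            "median_summary", n_perm = 1000,
                            alphas = c(0.05, 0.01), seed = 12)
message("group d-prime medians per type, against the permutation threshold")
print(round(pn$observed, 3))
message("one-sided thresholds: ",
        paste(sprintf("%s = %.3f", rownames(pn$thresholds),
                      pn$thresholds[, 1]), collapse = ", "))
print(pn$flagged)

mean_z <- 0
for (cohort in 1:5) {
  beh <- simulate_behavior(snr_tab, cfg, n_participants = 19,
                           seed = cohort_seeds[cohort])
  dp <- suppressWarnings(dprime_table(beh, on_boundary = "drop"))
  mean_z <- mean_z + suppressWarnings(
    snr_behavior_correlation(dp, snr_mat))$mean_z / 5
}
curve <- data.frame(window_ms = as.numeric(colnames(snr_mat)),
                    mean_z = mean_z)
print(round(curve, 3))
write.csv(curve, "results/behavior_snr_correlation.csv", row.names = FALSE)

message("findings: d-prime tracks the type-mean 30-ms local SNR; the ",
        "d'-SNR correlation declines from short to long analysis windows ",
        sprintf("(z %.2f at 30 ms vs %.2f at 500 ms)",
                curve$mean_z[1], curve$mean_z[9]))
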