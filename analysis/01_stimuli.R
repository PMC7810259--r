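#!/usr/bin/env Rscript
# Step 1: synthesize the full AM stimulus set.
#
# Six stimulus families (1/f modulation spectra with exponents 0.5-2 plus
# a speech-shaped spectrum), 60 five-second stimuli each, half carrying a
# 1-kHz probe tone at -10 dB global SNR. Verifies the construction
# invariants and checks that the synthesized envelopes preserve the
# generating exponents.

library(modtrf)

master_seed <- 1
dir.create("results", showWarnings = FALSE)

message("building 360 AM stimuli (master seed ", master_seed, ") ...")
set <- build_stimulus_set(master_seed = master_seed)
print(set)

depths <- vapply(set$stimuli, function(st) {
  c(min(st$envelope$samples), max(st$envelope$samples))
}, numeric(2))
stopifnot(all(depths[1, ] == 0), all(depths[2, ] == 1))
message("every envelope has exact 100% modulation depth")

fits <- type_modulation_spectra(set, source = "envelope")
print(fits)
write.csv(fits, "results/exponents_envelope.csv", row.names = FALSE)
write.table(set$manifest, "results/stimulus_manifest.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("findings: the 2-20 Hz log-log slopes of the mean envelope spectra ",
        "match the generating exponents to within ",
        sprintf("%.3f", max(abs(fits$exponent_fit[fits$am_type != "speech"] -
                                  c(0.5, 0.75, 1, 1.5, 2)))),
        "; manifest written to results/stimulus_manifest.tsv")
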