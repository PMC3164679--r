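#!/usr/bin/env Rscript
# Step 5 — noise robustness (Experiment 3).
#
# White noise scaled to each utterance's waveform standard deviation corrupts
# the audio at increasing levels; audio and reconstructed-motor features are
# recomputed from the noisy signal (the audio-motor map is retrained per
# level on the noisy training side with clean kinematic targets), while
# real-motor features are untouched. Output: results/noise/.

source("analysis/_common.R")

corpus <- load_corpus()
segs <- load_segments()
splits <- make_splits(segs, "overall", k = CFG$experiments$overall_k,
                      seed = SEED, val_frac = CFG$experiments$amm_val_frac)

levels <- c(0, 0.5, 1, 2)
rn <- run_noise_experiment(corpus, segs, splits, levels = levels,
                           replicates = 5,
                           feature_sets = c("audio", "real", "reconstructed",
                                            "joint"),
                           cfg = CFG, seed = SEED)
write_results(rn, file.path(RESULTS_DIR, "noise"), CFG, SEED)

s <- rn$summary[order(rn$summary$level, rn$summary$feature_set), ]
cat("balanced error by noise level (x utterance sd):\n")
print(s[, c("level", "feature_set", "mean", "sem")], row.names = FALSE)

real_by_level <- s$mean[s$feature_set == "real"]
cat("\nreal-motor error identical across levels:",
    all(real_by_level == real_by_level[1]), "\n")
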