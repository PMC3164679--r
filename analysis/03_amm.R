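#!/usr/bin/env Rscript
# Step 3 — train and evaluate the audio-motor map.
#
# Per split of the overall schema, a feed-forward network learns to map
# sliding Mel-spectrogram contexts to (vlio, alio, vttu, attu); held-out
# NRMSE is compared with the mean-predictor baseline, and per-segment
# real-vs-reconstructed correlations are contrasted by plosive class — the
# double-dissociation analysis. Output: results/amm_nrmse.csv,
# results/amm_dissociation.csv.

source("analysis/_common.R")

corpus <- load_corpus()
segs <- load_segments()
splits <- make_splits(segs, "overall", k = CFG$experiments$overall_k,
                      seed = SEED, val_frac = CFG$experiments$amm_val_frac)

ev <- run_amm_evaluation(corpus, segs, splits, CFG, seed = SEED)
write_result_csv(ev$nrmse, file.path(RESULTS_DIR, "amm_nrmse.csv"), CFG, SEED)
write_result_csv(ev$dissociation$tests,
                 file.path(RESULTS_DIR, "amm_dissociation.csv"), CFG, SEED)

agg <- aggregate(cbind(nrmse, baseline_nrmse) ~ channel, ev$nrmse, mean)
cat("mean held-out NRMSE (vs mean-predictor baseline):\n")
print(agg, row.names = FALSE)
cat("trained map beats the baseline on every channel and split:",
    all(ev$nrmse$nrmse < ev$nrmse$baseline_nrmse), "\n\n")
cat("double dissociation (per-segment r grouped by class):\n")
print(ev$dissociation$tests[, c("channel", "favored", "mean_favored",
                                "mean_other", "t", "p")], row.names = FALSE)
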