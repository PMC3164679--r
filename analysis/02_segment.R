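#!/usr/bin/env Rscript
# Step 2 — detect and vet plosion segments.
#
# Scans both articulator-distance channels of every utterance for the
# kinematic plosion signature (velocity zero-crossing with positive
# acceleration up to the velocity peak), vets candidates against the
# ground-truth intervals, and reports detection fidelity. Output:
# results/segments.csv and results/segmentation_fidelity.csv.

source("analysis/_common.R")

corpus <- load_corpus()
segs <- segment_corpus(corpus, c("lio", "ttu"), vet = "truth", CFG)
write_segments(segs, file.path(RESULTS_DIR, "segments.csv"), CFG, SEED)

man <- corpus$manifest[match(segs$utterance_id, corpus$manifest$utterance_id), ]
fidelity <- data.frame(
  n_utterances = nrow(corpus$manifest),
  n_accepted = nrow(segs),
  recall = length(unique(segs$utterance_id)) / nrow(corpus$manifest),
  t1_max_error_samples = max(abs(segs$t1_s - man$truth_t1_s)) * CFG$fs_motor,
  t2_max_error_samples = max(abs(segs$t2_s - man$truth_t2_s)) * CFG$fs_motor,
  wrong_channel_accepted = sum(segs$channel != critical_channel(segs$class))
)
write_result_csv(fidelity, file.path(RESULTS_DIR, "segmentation_fidelity.csv"),
                 CFG, SEED)

cat("accepted", nrow(segs), "segments;",
    "recall", round(fidelity$recall, 4),
    "| worst t1 error", round(fidelity$t1_max_error_samples, 2), "samples",
    "| wrong-channel accepts", fidelity$wrong_channel_accepted, "\n")
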