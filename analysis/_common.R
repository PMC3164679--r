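# Shared settings for the analysis scripts. Everything is a pure function of
# (SEED, CFG); rerunning any script reproduces its outputs byte for byte.

library(motorinv)

SEED <- 42
CORPUS_DIR <- "scratch/corpus"
RESULTS_DIR <- "results"

# Study conditions: 6 speakers, the full balanced design (336 utterances).
# The audio-motor map and the SVM grid run at the reduced sizes documented in
# the methods vignette (vignettes/motor-invariants.Rmd).
CFG <- mi_config(list(
  classify = list(cost_grid = c(1, 100), gamma_grid = c(0.001, 0.01, 0.1)),
  amm = list(n_mel = 16, context_slices = 7, hidden_units = 16,
             restarts = 2, epochs_per_check = 30, max_checks = 8,
             early_stop_patience = 2, max_train_samples = 1500)
))

load_corpus <- function() {
  manifest <- file.path(CORPUS_DIR, "manifest.csv")
  if (!file.exists(manifest)) {
    stop("corpus not found; run analysis/01_simulate.R first")
  }
  read_corpus(manifest, CFG)
}

load_segments <- function() {
  path <- file.path(RESULTS_DIR, "segments.csv")
  if (!file.exists(path)) stop("segments not found; run analysis/02_segment.R")
  read_result_csv(path)
}
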