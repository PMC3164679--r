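# Shared fixtures: corpora are generated in code and cached per test run so
# several test files can reuse them without repeated synthesis.

.fixture_env <- new.env(parent = emptyenv())

# configuration used throughout the tests: reduced audio-motor-map and SVM
# grid sizes keep network training and grid search fast while exercising the
# same code paths as the full-size defaults
test_config <- function(overrides = list()) {
  base <- list(
    classify = list(cost_grid = c(1, 100), gamma_grid = c(0.001, 0.01, 0.1)),
    amm = list(n_mel = 16, context_slices = 7, hidden_units = 16,
               restarts = 2, epochs_per_check = 30, max_checks = 8,
               early_stop_patience = 2, max_train_samples = 1500)
  )
  for (k in names(overrides)) {
    base[[k]] <- utils::modifyList(base[[k]] %||% list(), overrides[[k]])
  }
  mi_config(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# small 2-speaker corpus (112 utterances) for fast pipeline tests
small_corpus <- function() {
  cached("small_corpus", make_corpus(2, 1, seed = 7, test_config()))
}

small_segments <- function() {
  cached("small_segments", {
    corpus <- small_corpus()
    segment_corpus(corpus, c("lio", "ttu"), vet = "truth", corpus$config)
  })
}

# the full 6-speaker study corpus (336 utterances) used by the acceptance
# checks; cached because several criteria share it
study_corpus <- function() {
  cached("study_corpus", make_corpus(6, 1, seed = 42, test_config()))
}

study_segments <- function() {
  cached("study_segments", {
    corpus <- study_corpus()
    segment_corpus(corpus, c("lio", "ttu"), vet = "truth", corpus$config)
  })
}

# a synthetic labeled segment table (no audio behind it) for split-construction
# tests that only need grouping metadata
fake_segment_table <- function(n_speakers = 6) {
  g <- expand.grid(speaker = paste0("spk", seq_len(n_speakers)),
                   consonant = c("b", "p", "d", "t"),
                   coart_phone = c("a", "e", "i", "o", "u", "r", "s"),
                   position = c("initial", "medial"),
                   stringsAsFactors = FALSE)
  g$class <- consonant_class(g$consonant)
  g$utterance_id <- sprintf("u%04d", seq_len(nrow(g)))
  g
}
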