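#' Default pipeline configuration
#'
#' Returns the full run configuration as a nested list, optionally modified by
#' `overrides` (a nested list with the same structure; unknown keys are
#' rejected). All tunable defaults of every stage live here so a run is a pure
#' function of (config, seed).
#'
#' Groups:
#' \describe{
#'   \item{fs_audio, fs_motor}{sampling rates in Hz (audio waveform,
#'     articulograph trajectories). Motor sample `k` is simultaneous with
#'     audio time `k / fs_motor`.}
#'   \item{synth}{acoustic and kinematic parameters of the synthetic corpus
#'     generator (see [make_corpus()]).}
#'   \item{kinematics}{smoothing window (odd sample count), plosion duration
#'     bounds in ms, and the two-sided overlap threshold used when vetting
#'     detected segments against ground truth.}
#'   \item{amm}{audio-motor-map extraction and training parameters: Hamming
#'     slice length/hop (ms), Mel filter count and band (Hz), context size in
#'     slices (odd), hidden units, random restarts, `reg_ratio` weighting MSE
#'     against mean squared weights in the regularized loss, early-stopping
#'     patience (validation checks), epochs between checks, and the sigmoid
#'     target range.}
#'   \item{features}{audio feature encoding: slice length (ms), number of
#'     slices per segment, cepstral coefficients per slice, Mel filters and
#'     band.}
#'   \item{classify}{RBF-SVM grid (`cost_grid`, `gamma_grid`) and the number
#'     of inner cross-validation folds used for grid search.}
#'   \item{experiments}{fold count of the `overall` schema, the fraction of
#'     training utterances held out for audio-motor-map early stopping, the
#'     additive-noise level grid (multiples of per-utterance waveform standard
#'     deviation), the number of noisy replicates per test utterance, and
#'     whether training-side audio also receives noise.}
#' }
#'
#' @param overrides nested list of values to override.
#' @return a `motorinv_config` list.
#' @examples
#' cfg <- mi_config(list(amm = list(hidden_units = 16)))
#' cfg$amm$hidden_units
#' @export
mi_config <- function(overrides = list()) {
  cfg <- list(
    fs_audio = 16000,
    fs_motor = 200,
    synth = list(
      lead_ms_range      = c(80, 160),  # open posture before closure onset
      approach_ms        = 80,          # closing gesture duration
      vowel_ms           = 250,         # following-phone duration
      tail_ms            = 60,
      hold_ms_range      = c(30, 80),   # closure hold, utterance-level jitter
      release_ms_range   = c(35, 60),   # t2 - t1, utterance-level jitter
      scale_range        = c(0.8, 1.3), # per-speaker articulator scale (mm multiplier)
      open_mm            = c(lio = 16, ttu = 10),
      closed_mm          = 0.3,
      noncrit_sd_mm      = 1.5,
      noncrit_cutoff_hz  = 0.6,
      pitch_hz_range     = c(160, 260),
      f1_range           = c(350, 550),
      f2_range           = c(1400, 2100),
      f3_range           = c(2500, 3200),
      burst_centroid_hz  = c(bilabial = 1100, dental = 3000),
      # formant-transition loci (NA = no glide for that formant)
      formant_locus_hz   = list(bilabial = c(NA, 800, 2300),
                                dental = c(NA, 1800, 2900)),
      burst_token_sd     = 0.25,   # log-normal token-level centroid jitter
      burst_amp          = 0.05,
      vowel_amp          = 0.85,
      voicing_amp        = 0.0015,
      floor_amp          = 0.0008
    ),
    kinematics = list(
      smoothing_window = 3,
      min_dur_ms       = 20,
      max_dur_ms       = 200,
      overlap_threshold = 0.5
    ),
    amm = list(
      win_ms             = 20,
      hop_ms             = 10,
      n_mel              = 24,
      band_hz            = c(100, 8000),
      context_slices     = 19,
      hidden_units       = 100,
      restarts           = 5,
      reg_ratio          = 0.95,
      early_stop_patience = 10,
      epochs_per_check   = 25,
      max_checks         = 40,
      max_train_samples  = Inf,
      target_range       = c(0.1, 0.9)
    ),
    features = list(
      slice_ms = 20,
      n_slices = 7,
      n_cep    = 13,
      n_mel    = 24,
      band_hz  = c(100, 8000)
    ),
    classify = list(
      cost_grid   = 2^seq(-5, 15, by = 2),
      gamma_grid  = 2^seq(-15, 3, by = 2),
      inner_folds = 5
    ),
    experiments = list(
      overall_k        = 6,
      amm_val_frac     = 0.1,
      noise_levels     = c(0.1, 0.25, 0.5, 0.75, 1.0, 1.5, 2.0),
      noise_replicates = 10,
      noise_on_train   = TRUE
    )
  )
  cfg <- merge_config(cfg, overrides, path = "config")
  validate_config(cfg)
  class(cfg) <- "motorinv_config"
  cfg
}

merge_config <- function(base, overrides, path) {
  if (length(overrides) == 0) return(base)
  stopifnot(is.list(overrides))
  keys <- names(overrides)
  if (is.null(keys) || any(keys == "")) {
    stop("config overrides must be named (at ", path, ")")
  }
  unknown <- setdiff(keys, names(base))
  if (length(unknown) > 0) {
    stop("unknown config key(s) at ", path, ": ", paste(unknown, collapse = ", "))
  }
  for (k in keys) {
    if (is.list(base[[k]]) && !is.list(overrides[[k]])) {
      stop("config key ", path, "$", k, " must be a list")
    }
    base[[k]] <- if (is.list(base[[k]])) {
      merge_config(base[[k]], overrides[[k]], paste0(path, "$", k))
    } else {
      v <- overrides[[k]]
      if (is.list(v)) v <- unlist(v)   # YAML maps come back as lists
      if (is.numeric(base[[k]]) && is.numeric(v)) storage.mode(v) <- "double"
      v
    }
  }
  base
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid config: ", msg)
  chk(cfg$fs_audio > 0 && cfg$fs_motor > 0, "sampling rates must be positive")
  chk(cfg$kinematics$smoothing_window %% 2 == 1, "smoothing_window must be odd")
  chk(cfg$kinematics$min_dur_ms < cfg$kinematics$max_dur_ms,
      "min_dur_ms must be below max_dur_ms")
  chk(cfg$amm$context_slices %% 2 == 1, "context_slices must be odd")
  tr <- cfg$amm$target_range
  chk(length(tr) == 2 && 0 < tr[1] && tr[1] < tr[2] && tr[2] < 1,
      "target_range must satisfy 0 < lo < hi < 1")
  chk(cfg$amm$reg_ratio > 0 && cfg$amm$reg_ratio <= 1,
      "reg_ratio must be in (0, 1]")
  chk(all(cfg$classify$cost_grid > 0) && all(cfg$classify$gamma_grid > 0),
      "SVM grid values must be positive")
  chk(all(cfg$experiments$noise_levels >= 0), "noise levels must be >= 0")
  chk(diff(cfg$amm$band_hz) > 0 && diff(cfg$features$band_hz) > 0,
      "band_hz must be increasing")
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' @param path file path.
#' @param cfg a `motorinv_config`.
#' @return `read_config` returns a validated `motorinv_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  mi_config(raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  # named atomic vectors become YAML maps so their names survive the trip
  namify <- function(x) {
    if (is.list(x)) lapply(x, namify)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(namify(unclass(cfg)), path, precision = 15)
  invisible(path)
}

#' Stable short hash of a configuration
#'
#' FNV-1a hash over the deparsed configuration, used to stamp result files so
#' outputs can be traced back to the exact settings that produced them.
#'
#' @param cfg a `motorinv_config` (or any R object).
#' @return an 8-hex-digit character scalar.
#' @export
config_hash <- function(cfg) {
  txt <- paste(deparse(unclass(cfg), control = "all"), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
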