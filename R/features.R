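#' @title Per-segment feature encodings
#'
#' @description
#' Each vetted plosion segment is encoded in one of four ways: *audio*
#' (Mel-cepstral coefficients with first- and second-order derivatives over
#' slices spread uniformly across the segment), *real motor* (the constant,
#' linear, quadratic and cubic coefficients of a least-squares cubic fit to
#' each of vlio, alio, vttu, attu on time normalized to `[0, 1]`),
#' *reconstructed motor* (the same cubic encoding applied to AMM-reconstructed
#' trajectories), and *joint* (a posterior-averaging fusion handled by
#' [joint_decision()]). The cubic fit captures the qualitative shape of the
#' plosive gesture while abstracting away from its duration.
#'
#' @name features
NULL

#' Least-squares cubic fit on normalized time
#'
#' Ordinary least squares of a degree-3 polynomial in `t` rescaled to
#' `[0, 1]` over the segment.
#'
#' @param signal numeric vector (>= 4 samples).
#' @return named numeric `(c0, c1, c2, c3)`.
#' @export
cubic_fit <- function(signal) {
  n <- length(signal)
  if (n < 4) stop("cubic fit needs at least 4 samples")
  t <- seq(0, 1, length.out = n)
  X <- cbind(1, t, t^2, t^3)
  cf <- stats::lm.fit(X, signal)$coefficients
  stats::setNames(as.numeric(cf), c("c0", "c1", "c2", "c3"))
}

#' Motor feature vector of a segment
#'
#' Concatenates the cubic-fit coefficients of the four kinematic channels in
#' fixed order (vlio, alio, vttu, attu): 16 values. `source = "real"` uses
#' the segment's measured kinematics; `source = "reconstructed"` uses a
#' supplied AMM reconstruction of the same shape.
#'
#' @param segment an [extract_segment()] result.
#' @param source `"real"` or `"reconstructed"`.
#' @param recon `n x 4` reconstructed matrix (required when
#'   `source = "reconstructed"`).
#' @return named numeric vector of length 16.
#' @export
motor_features <- function(segment, source = c("real", "reconstructed"),
                           recon = NULL) {
  source <- match.arg(source)
  km <- if (source == "real") segment$kin else recon
  if (is.null(km)) stop("reconstructed source requires a reconstruction matrix")
  if (ncol(km) != 4) stop("kinematic matrix must have 4 channels")
  chans <- c("vlio", "alio", "vttu", "attu")
  out <- numeric(0)
  for (k in 1:4) {
    cf <- cubic_fit(km[, k])
    names(cf) <- paste0(chans[k], "_", names(cf))
    out <- c(out, cf)
  }
  out
}

# finite differences across slices with one-sided ends (rows = slices)
slice_deltas <- function(m) {
  n <- nrow(m)
  d <- m * 0
  if (n == 1) return(d)
  if (n > 2) d[2:(n - 1), ] <- (m[3:n, , drop = FALSE] - m[1:(n - 2), , drop = FALSE]) / 2
  d[1, ] <- m[2, ] - m[1, ]
  d[n, ] <- m[n, ] - m[n - 1, ]
  d
}

#' Audio feature vector of a segment
#'
#' `n_slices` slice-start times are spaced uniformly so the slices cover the
#' segment end-to-end: they overlap when the segment is shorter than
#' `n_slices * slice_ms` and leave gaps when it is longer. Each slice yields
#' `n_cep` Mel-cepstral coefficients over `band_hz`; first- and second-order
#' derivatives are taken across slices (one-sided at the ends). The encoding
#' has fixed length `n_slices * n_cep * 3` regardless of segment duration,
#' concatenated slice by slice as (static, delta, delta-delta). Audio shorter
#' than one slice is zero-padded and the result flagged with attribute
#' `padded`.
#'
#' @param audio segment waveform.
#' @param fs sampling rate (Hz).
#' @param cfg the `features` group of [mi_config()].
#' @return numeric vector of length `n_slices * n_cep * 3`.
#' @export
audio_features <- function(audio, fs, cfg = mi_config()$features) {
  if (length(audio) == 0) stop("empty audio segment")
  slice_len <- round(cfg$slice_ms / 1000 * fs)
  padded <- FALSE
  if (length(audio) < slice_len) {
    audio <- c(audio, numeric(slice_len - length(audio)))
    padded <- TRUE
  }
  ns <- cfg$n_slices
  starts <- if (ns == 1) 0 else round(seq(0, length(audio) - slice_len, length.out = ns))
  nfft <- 2^ceiling(log2(slice_len))
  fb <- mel_filterbank(cfg$n_mel, nfft, fs, cfg$band_hz)
  hamm <- 0.54 - 0.46 * cos(2 * pi * (0:(slice_len - 1)) / (slice_len - 1))
  logmel <- matrix(0, ns, cfg$n_mel)
  for (s in seq_len(ns)) {
    x <- audio[starts[s] + seq_len(slice_len)] * hamm
    spec <- Mod(stats::fft(c(x, numeric(nfft - slice_len))))[1:(nfft / 2 + 1)]^2
    logmel[s, ] <- log(pmax(as.numeric(fb %*% spec), 1e-10))
  }
  cep <- mel_cepstra(logmel, cfg$n_cep)
  d1 <- slice_deltas(cep)
  d2 <- slice_deltas(d1)
  out <- as.numeric(t(cbind(cep, d1, d2)))
  names(out) <- paste0("s", rep(seq_len(ns), each = 3 * cfg$n_cep), "_",
                       rep(c(rep("c", cfg$n_cep), rep("d", cfg$n_cep),
                             rep("dd", cfg$n_cep)), ns),
                       rep(seq_len(cfg$n_cep) - 1, 3 * ns))
  attr(out, "padded") <- padded
  out
}

#' Aligned segment objects for a segment table
#'
#' @param corpus a corpus.
#' @param segments a [segment_corpus()] table.
#' @param cfg a [mi_config()] list.
#' @return named list of [extract_segment()] results (one per row), named by
#'   `utterance_id`.
#' @export
align_segments <- function(corpus, segments, cfg = corpus$config) {
  out <- lapply(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    extract_segment(corpus$utterances[[seg$utterance_id]], seg,
                    window = cfg$kinematics$smoothing_window)
  })
  names(out) <- segments$utterance_id
  out
}

#' Feature matrix for a set of aligned segments
#'
#' @param aligned list from [align_segments()].
#' @param set `"audio"`, `"real"` or `"reconstructed"`.
#' @param cfg a [mi_config()] list.
#' @param model an `amm_model` (required for `"reconstructed"`).
#' @return numeric matrix, one row per segment.
#' @export
feature_matrix <- function(aligned, set = c("audio", "real", "reconstructed"),
                           cfg = mi_config(), model = NULL) {
  set <- match.arg(set)
  rows <- lapply(aligned, function(seg) {
    switch(set,
      audio = audio_features(seg$audio, seg$fs_audio, cfg$features),
      real = motor_features(seg, "real"),
      reconstructed = {
        if (is.null(model)) stop("reconstructed features require an AMM model")
        times <- seg$motor_idx / seg$fs_motor
        rec <- reconstruct_motor(model, seg$utt_audio, times, seg$fs_audio)
        motor_features(seg, "reconstructed", recon = rec)
      })
  })
  do.call(rbind, rows)
}
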