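#' @title Articulator kinematics and plosion detection
#'
#' @description
#' A plosion is the kinematic signature of a stop consonant's release on an
#' articulator-distance signal `d(t)` (lips opening for bilabials,
#' tongue-tip-to-upper-teeth distance for dentals): the interval from `t1`,
#' the opening onset where velocity is zero and acceleration positive, to
#' `t2`, the instant of maximum opening velocity where acceleration crosses
#' zero. Segments are cut at `t2` (the velocity peak) rather than at maximum
#' opening so that they capture the plosion only, with as little of the
#' following phone as possible.
#'
#' @name kinematics
NULL

# central differences with one-sided endpoints, scaled by the sampling rate
central_diff <- function(x, fs) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples to differentiate")
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  v[1] <- (x[2] - x[1]) * fs
  v[n] <- (x[n] - x[n - 1]) * fs
  v
}

#' Per-sample Euclidean distance between two 3D sensor trajectories
#'
#' Articulator-distance channels (lips opening, tongue-tip-to-teeth) are the
#' Euclidean distances between pairs of articulograph sensors.
#'
#' @param s1,s2 numeric matrices (n x 3) of sensor positions in mm.
#' @param fs sampling rate in Hz.
#' @param name channel name (`"lio"` or `"ttu"`).
#' @return a `motor_channel` list: `name`, `d` (mm), `fs`.
#' @export
euclidean_distance <- function(s1, s2, fs, name = "lio") {
  s1 <- as.matrix(s1); s2 <- as.matrix(s2)
  if (!all(dim(s1) == dim(s2))) stop("sensor trajectories must have equal dimensions")
  if (ncol(s1) != 3) stop("sensor trajectories must be n x 3")
  d <- sqrt(rowSums((s1 - s2)^2))
  motor_channel(name, d, fs)
}

#' Construct a motor channel
#'
#' @param name `"lio"` or `"ttu"`.
#' @param d distance samples (mm), finite.
#' @param fs sampling rate (Hz).
#' @export
motor_channel <- function(name, d, fs) {
  if (!name %in% c("lio", "ttu")) stop("channel name must be 'lio' or 'ttu'")
  if (!(is.numeric(fs) && fs > 0)) stop("fs must be positive")
  if (!all(is.finite(d))) stop("distance samples must be finite")
  structure(list(name = name, d = as.numeric(d), fs = fs), class = "motor_channel")
}

#' Smooth a distance channel and differentiate it twice
#'
#' Centered moving-average smoothing (odd window), then central-difference
#' velocity and acceleration scaled by the sampling rate; endpoints use
#' one-sided differences and shrinking averaging windows.
#'
#' @param ch a [motor_channel()].
#' @param window odd positive window length in samples (`1` disables
#'   smoothing).
#' @return a `kinematic_derivatives` list: `d_smooth`, `v` (mm/s), `a`
#'   (mm/s^2), `fs`, `smoothing_window`, `channel`.
#' @export
smooth_and_differentiate <- function(ch, window = 3) {
  stopifnot(inherits(ch, "motor_channel"))
  if (window %% 2 != 1 || window < 1) stop("smoothing window must be odd and >= 1")
  d <- ch$d
  n <- length(d)
  if (window >= n) stop("smoothing window must be shorter than the signal")
  if (window == 1) {
    ds <- d
  } else {
    half <- (window - 1) / 2
    ds <- as.numeric(stats::filter(d, rep(1 / window, window), sides = 2))
    for (i in seq_len(half)) {
      ds[i] <- mean(d[1:(i + half)])
      ds[n - i + 1] <- mean(d[(n - i + 1 - half):n])
    }
  }
  v <- central_diff(ds, ch$fs)
  a <- central_diff(v, ch$fs)
  structure(list(d_smooth = ds, v = v, a = a, fs = ch$fs,
                 smoothing_window = window, channel = ch$name),
            class = "kinematic_derivatives")
}

# linear-interpolation location of a zero crossing between samples i and i+1
# (R 1-based indices); returns fractional 1-based position
interp_crossing <- function(y0, y1, i) {
  if (y1 == y0) return(i)
  i + y0 / (y0 - y1) * 1  # y0 and y1 straddle zero
}

#' Detect plosion candidates on a kinematic channel
#'
#' A candidate starts at an upward zero crossing of velocity with positive
#' acceleration (`t1`) and ends at the first subsequent downward zero
#' crossing of acceleration, i.e. the local velocity maximum (`t2`). Zero
#' crossings are located by linear interpolation between samples and snapped
#' to the nearest sample index. Only candidates whose duration lies within
#' `[min_dur_ms, max_dur_ms]` are returned, ordered by `t1`.
#'
#' @param kin a [smooth_and_differentiate()] result.
#' @param min_dur_ms,max_dur_ms duration bounds in milliseconds.
#' @return data.frame with columns `channel`, `t1_idx`, `t2_idx` (0-based
#'   motor sample indices), `t1_s`, `t2_s`. Empty if no candidate qualifies.
#' @export
detect_plosions <- function(kin, min_dur_ms = 20, max_dur_ms = 200) {
  stopifnot(inherits(kin, "kinematic_derivatives"))
  v <- kin$v; a <- kin$a; fs <- kin$fs
  n <- length(v)
  out <- list()
  i <- 1
  up <- which(v[-n] <= 0 & v[-1] > 0)
  for (i0 in up) {
    x1 <- interp_crossing(v[i0], v[i0 + 1], i0)      # fractional 1-based
    a_at <- a[i0] + (a[i0 + 1] - a[i0]) * (x1 - i0)
    if (!(a_at > 0)) next
    t1_idx <- round(x1) - 1                           # 0-based snap
    # first subsequent downward zero crossing of acceleration
    j_all <- which(a[-n] > 0 & a[-1] <= 0)
    j_all <- j_all[j_all >= x1]
    if (length(j_all) == 0) next
    j0 <- j_all[1]
    x2 <- interp_crossing(a[j0], a[j0 + 1], j0)
    t2_idx <- round(x2) - 1
    if (t2_idx <= t1_idx) next
    dur_ms <- (x2 - x1) / fs * 1000
    if (dur_ms < min_dur_ms || dur_ms > max_dur_ms) next
    out[[length(out) + 1]] <- data.frame(
      channel = kin$channel, t1_idx = t1_idx, t2_idx = t2_idx,
      t1_s = t1_idx / fs, t2_s = t2_idx / fs, stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(channel = character(), t1_idx = integer(),
                      t2_idx = integer(), t1_s = numeric(), t2_s = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$t1_s), , drop = FALSE]
}

overlap_frac <- function(a1, a2, b1, b2) {
  inter <- max(0, min(a2, b2) - max(a1, b1))
  c(inter / max(a2 - a1, 1e-12), inter / max(b2 - b1, 1e-12))
}

#' Vet plosion candidates
#'
#' The corpus the method was designed for was segmented semi-automatically:
#' every candidate matching the kinematic conditions was played back and an
#' experimenter accepted or rejected it. Here that judgment is replaced by
#' either (a) comparison with ground-truth intervals — a candidate is
#' accepted when it overlaps a true interval by at least `threshold` in both
#' directions — or (b) a caller-supplied `accept_fn`, or (c) accept-all.
#' Accepted candidates are labeled from the matched truth row.
#'
#' @param candidates data.frame from [detect_plosions()].
#' @param truth optional data.frame with `t1_s`, `t2_s`, `channel` and label
#'   columns (`consonant`, `class`, `speaker`, `coart_phone`, ...).
#' @param accept_fn optional `function(candidate_row) -> logical`.
#' @param threshold two-sided overlap threshold (fraction of each interval).
#' @return the accepted subset of `candidates`, with label columns attached
#'   in truth mode.
#' @export
vet_segments <- function(candidates, truth = NULL, accept_fn = NULL,
                         threshold = 0.5) {
  if (!is.null(truth) && !is.null(accept_fn)) {
    stop("supply at most one of truth / accept_fn")
  }
  if (nrow(candidates) == 0) return(candidates)
  if (is.null(truth) && is.null(accept_fn)) return(candidates)
  if (!is.null(accept_fn)) {
    keep <- vapply(seq_len(nrow(candidates)),
                   function(i) isTRUE(accept_fn(candidates[i, ])), logical(1))
    return(candidates[keep, , drop = FALSE])
  }
  label_cols <- setdiff(names(truth), c("t1_s", "t2_s", "channel"))
  matched <- integer(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    for (j in seq_len(nrow(truth))) {
      if (!is.null(truth$channel) && truth$channel[j] != candidates$channel[i]) next
      ov <- overlap_frac(candidates$t1_s[i], candidates$t2_s[i],
                         truth$t1_s[j], truth$t2_s[j])
      if (all(ov >= threshold)) { matched[i] <- j; break }
    }
  }
  keep <- matched > 0
  res <- candidates[keep, , drop = FALSE]
  if (nrow(res) > 0 && length(label_cols) > 0) {
    res <- cbind(res, truth[matched[keep], label_cols, drop = FALSE])
    rownames(res) <- NULL
  }
  res
}

#' Full kinematic derivatives of one utterance
#'
#' @param utt a `synthetic_utterance` (or loaded utterance with `lio`, `ttu`,
#'   `fs_motor`).
#' @param window smoothing window in samples.
#' @return list of [smooth_and_differentiate()] results, `lio` and `ttu`.
#' @export
utterance_kinematics <- function(utt, window = 3) {
  list(
    lio = smooth_and_differentiate(motor_channel("lio", utt$lio, utt$fs_motor), window),
    ttu = smooth_and_differentiate(motor_channel("ttu", utt$ttu, utt$fs_motor), window)
  )
}

#' Extract the aligned audio/kinematic segment for a vetted plosion
#'
#' Restricts the four kinematic channels (vlio, alio, vttu, attu) to the
#' closed motor-sample interval `[t1_idx, t2_idx]` and cuts the audio window
#' `[t1_s, t2_s]` at the audio rate (length `round((t2_s - t1_s) * fs_audio)`
#' samples).
#'
#' @param utt utterance with `audio`, `lio`, `ttu`, `fs_audio`, `fs_motor`.
#' @param seg one row of a vetted segment table (needs `t1_idx`, `t2_idx`).
#' @param window smoothing window used for the derivatives.
#' @param kin optional precomputed [utterance_kinematics()] result.
#' @return an `aligned_segment` list: `audio`, `kin` (n x 4 matrix, columns
#'   vlio, alio, vttu, attu), `motor_idx` (0-based), `t1_s`, `t2_s`, `meta`
#'   (label columns of `seg`), `fs_audio`, `fs_motor`.
#' @export
extract_segment <- function(utt, seg, window = 3, kin = NULL) {
  t1i <- as.integer(seg$t1_idx); t2i <- as.integer(seg$t2_idx)
  n_motor <- length(utt$lio)
  if (t1i < 0 || t2i >= n_motor || t1i >= t2i) {
    stop("segment [", t1i, ", ", t2i, "] out of bounds for ", n_motor, " motor samples")
  }
  if (is.null(kin)) kin <- utterance_kinematics(utt, window)
  ix <- (t1i:t2i) + 1
  km <- cbind(vlio = kin$lio$v[ix], alio = kin$lio$a[ix],
              vttu = kin$ttu$v[ix], attu = kin$ttu$a[ix])
  t1_s <- t1i / utt$fs_motor
  t2_s <- t2i / utt$fs_motor
  a_start <- round(t1_s * utt$fs_audio) + 1
  a_len <- round((t2_s - t1_s) * utt$fs_audio)
  if (a_start + a_len - 1 > length(utt$audio)) {
    stop("audio window exceeds waveform length")
  }
  meta_cols <- setdiff(names(seg), c("t1_idx", "t2_idx", "t1_s", "t2_s"))
  structure(list(
    audio = utt$audio[a_start:(a_start + a_len - 1)],
    utt_audio = utt$audio,
    kin = km, motor_idx = t1i:t2i, t1_s = t1_s, t2_s = t2_s,
    meta = as.list(seg[meta_cols]),
    fs_audio = utt$fs_audio, fs_motor = utt$fs_motor
  ), class = "aligned_segment")
}

#' Detect and vet plosion segments over a whole corpus
#'
#' Runs detection on the requested channel(s) of every utterance and vets
#' candidates against the corpus ground truth (the true plosion interval on
#' the critical channel, labeled with the utterance metadata). With
#' `vet = "all"`, every kinematic candidate is kept unvetted.
#'
#' @param corpus a [make_corpus()] result (or loaded corpus of the same
#'   shape).
#' @param channels channels to scan: `"lio"`, `"ttu"` or both.
#' @param vet `"truth"` or `"all"`.
#' @param cfg a [mi_config()] list (smoothing window, duration bounds,
#'   overlap threshold).
#' @return data.frame of accepted segments: `utterance_id`, `channel`,
#'   `t1_idx`, `t2_idx`, `t1_s`, `t2_s`, plus labels (`consonant`, `class`,
#'   `speaker`, `coart_phone`, `position`) in truth mode.
#' @export
segment_corpus <- function(corpus, channels = c("lio", "ttu"), vet = "truth",
                           cfg = corpus$config) {
  kc <- cfg$kinematics
  rows <- list()
  for (id in corpus$manifest$utterance_id) {
    utt <- corpus$utterances[[id]]
    man <- corpus$manifest[corpus$manifest$utterance_id == id, ]
    kin <- utterance_kinematics(utt, kc$smoothing_window)
    for (ch in channels) {
      cand <- detect_plosions(kin[[ch]], kc$min_dur_ms, kc$max_dur_ms)
      if (nrow(cand) == 0) next
      if (vet == "truth") {
        truth <- data.frame(
          t1_s = man$truth_t1_s, t2_s = man$truth_t2_s,
          channel = critical_channel(man$class),
          consonant = man$consonant, class = man$class, speaker = man$speaker,
          coart_phone = man$coart_phone, position = man$position,
          stringsAsFactors = FALSE
        )
        cand <- vet_segments(cand, truth = truth, threshold = kc$overlap_threshold)
      }
      if (nrow(cand) == 0) next
      cand <- cbind(utterance_id = id, cand, stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- cand
    }
  }
  if (length(rows) == 0) {
    return(data.frame(utterance_id = character(), channel = character(),
                      t1_idx = integer(), t2_idx = integer(),
                      t1_s = numeric(), t2_s = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
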