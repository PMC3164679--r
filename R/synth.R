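#' @title Synthetic articulograph corpus generation
#'
#' @description
#' The corpus this analysis was designed for — six speakers recorded with an
#' electromagnetic articulograph while uttering words containing /b/, /p/,
#' /d/ or /t/ — is not publicly available. This module generates seeded
#' synthetic stand-ins that emulate the statistical structure the analysis
#' relies on:
#'
#' * a *critical* articulator-distance channel (`lio`, lips opening, for
#'   bilabials; `ttu`, tongue-tip-to-upper-teeth, for dentals) that executes a
#'   closure, a hold near zero aperture, and a release whose opening velocity
#'   is a raised-cosine bell — the plosion, with ground-truth landmarks
#'   `t1` (velocity zero, acceleration positive) and `t2` (velocity peak);
#' * a *non-critical* channel that is a smooth, landmark-free band-limited
#'   random trajectory;
#' * per-speaker scale and timing variability, and coarticulation-dependent
#'   following-phone acoustics;
#' * audio that deterministically encodes the critical articulator's state:
#'   silence during closure (plus a faint voicing bar for /b/, /d/), a release
#'   burst whose envelope follows the critical channel's opening velocity and
#'   whose spectral centroid is class-dependent (low for bilabial, high for
#'   dental), then a following phone with formants set by the coarticulating
#'   phone and the speaker.
#'
#' @name synth
NULL

CONSONANTS <- c("b", "p", "d", "t")
COART_PHONES <- c("a", "e", "i", "o", "u", "r", "s")
POSITIONS <- c("initial", "medial")

# canonical F2 locus per coarticulating phone (Hz), used to perturb the burst
PHONE_F2 <- c(a = 1300, e = 2000, i = 2300, o = 900, u = 800, r = 1400, s = 2600)

PHONE_FORMANTS <- list(
  a = c(800, 1300, 2600), e = c(500, 2000, 2800), i = c(320, 2300, 3000),
  o = c(450, 900, 2700), u = c(350, 800, 2600), r = c(350, 1400, 1650)
)

#' Map a consonant to its plosive class
#'
#' @param consonant character vector over \{b, p, d, t\}.
#' @return `"bilabial"` for /b/, /p/; `"dental"` for /d/, /t/.
#' @export
consonant_class <- function(consonant) {
  if (!all(consonant %in% CONSONANTS)) {
    stop("unknown consonant(s): ", paste(setdiff(consonant, CONSONANTS), collapse = ", "))
  }
  ifelse(consonant %in% c("b", "p"), "bilabial", "dental")
}

#' Critical articulator channel for a plosive class
#'
#' @param class character vector over \{bilabial, dental\}.
#' @return `"lio"` for bilabial, `"ttu"` for dental.
#' @export
critical_channel <- function(class) {
  stopifnot(all(class %in% c("bilabial", "dental")))
  ifelse(class == "bilabial", "lio", "ttu")
}

#' Create a synthetic speaker profile
#'
#' Draws articulator scales, plosion timing statistics, base formants and
#' pitch from documented ranges (see [mi_config()]), deterministically for a
#' given seed. Speakers differ in articulator size (which scales distances
#' and, inversely, burst resonance frequencies), in plosion timing, and in
#' voice characteristics.
#'
#' @param seed non-negative integer.
#' @param overrides named list replacing drawn fields (validated).
#' @param cfg a [mi_config()] list.
#' @return a `speaker_profile` list with fields `speaker_id`,
#'   `articulator_scale` (named `lio`/`ttu` multipliers), `release_ms`
#'   (`mean`, `jitter`), `hold_ms` (`mean`, `jitter`), `base_formants_hz`,
#'   `pitch_hz`, `rng_seed`.
#' @export
make_speaker <- function(seed, overrides = list(), cfg = mi_config()) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  sc <- cfg$synth
  prof <- with_seed(derive_seed(seed, "speaker_profile"), {
    rel_lo <- sc$release_ms_range[1]; rel_hi <- sc$release_ms_range[2]
    hold_lo <- sc$hold_ms_range[1]; hold_hi <- sc$hold_ms_range[2]
    list(
      speaker_id = paste0("spk", seed),
      articulator_scale = c(
        lio = stats::runif(1, sc$scale_range[1], sc$scale_range[2]),
        ttu = stats::runif(1, sc$scale_range[1], sc$scale_range[2])
      ),
      release_ms = list(
        mean = stats::runif(1, rel_lo + 0.15 * (rel_hi - rel_lo),
                            rel_hi - 0.15 * (rel_hi - rel_lo)),
        jitter = 0.08 * (rel_hi - rel_lo)
      ),
      hold_ms = list(
        mean = stats::runif(1, hold_lo + 0.15 * (hold_hi - hold_lo),
                            hold_hi - 0.15 * (hold_hi - hold_lo)),
        jitter = 0.1 * (hold_hi - hold_lo)
      ),
      base_formants_hz = c(
        stats::runif(1, sc$f1_range[1], sc$f1_range[2]),
        stats::runif(1, sc$f2_range[1], sc$f2_range[2]),
        stats::runif(1, sc$f3_range[1], sc$f3_range[2])
      ),
      pitch_hz = stats::runif(1, sc$pitch_hz_range[1], sc$pitch_hz_range[2]),
      rng_seed = as.integer(seed)
    )
  })
  known <- names(prof)
  unknown <- setdiff(names(overrides), known)
  if (length(unknown) > 0) stop("unknown profile field(s): ", paste(unknown, collapse = ", "))
  prof[names(overrides)] <- overrides
  validate_speaker(prof)
  structure(prof, class = "speaker_profile")
}

validate_speaker <- function(prof) {
  if (!all(prof$articulator_scale > 0)) stop("articulator_scale must be > 0")
  if (!(prof$release_ms$mean > 0)) stop("release duration must be > 0")
  if (!(prof$hold_ms$mean > 0)) stop("hold duration must be > 0")
  f <- prof$base_formants_hz
  if (length(f) != 3 || any(diff(f) <= 0)) stop("formants must be strictly increasing")
  if (!(prof$pitch_hz > 0)) stop("pitch must be > 0")
  invisible(prof)
}

#' Plan a balanced synthetic corpus
#'
#' Produces one utterance plan per cell of the fully crossed design
#' speaker x consonant \{b,p,d,t\} x coarticulating phone
#' \{a,e,i,o,u,r,s\} x word position \{initial, medial\}, replicated
#' `per_cell` times; total `n_speakers * 4 * 7 * 2 * per_cell` plans. Balance
#' is exact by construction, so bilabial and dental counts are always equal.
#'
#' @param n_speakers number of speakers (>= 1).
#' @param per_cell replicates per design cell (>= 1).
#' @param seed master seed; each plan receives a derived `seed` of its own.
#' @return data.frame of `utterance_plan` rows: `speaker_idx`, `consonant`,
#'   `class`, `coart_phone`, `position`, `rep`, `seed`.
#' @export
plan_corpus <- function(n_speakers, per_cell, seed) {
  stopifnot(n_speakers >= 1, per_cell >= 1)
  plans <- expand.grid(
    rep = seq_len(per_cell),
    position = POSITIONS,
    coart_phone = COART_PHONES,
    consonant = CONSONANTS,
    speaker_idx = seq_len(n_speakers),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  plans <- plans[, c("speaker_idx", "consonant", "coart_phone", "position", "rep")]
  plans$class <- consonant_class(plans$consonant)
  plans$seed <- vapply(seq_len(nrow(plans)), function(i) {
    derive_seed(seed, "utterance", i)
  }, integer(1))
  plans
}

# piecewise C2 plosion trajectory on the motor grid: open posture, closing
# bell, exact-zero-velocity hold, opening raised-cosine velocity bell, open.
# t1 = release onset, t2 = velocity peak (t1 + release_s).
plosion_distance <- function(t, lead_s, approach_s, hold_s, release_s,
                             open_mm, closed_mm) {
  t_close <- lead_s
  t_hold <- lead_s + approach_s
  t1 <- t_hold + hold_s
  t_open_end <- t1 + 2 * release_s
  A <- open_mm - closed_mm
  d <- numeric(length(t))
  d[t < t_close] <- open_mm
  ix <- t >= t_close & t < t_hold
  # closing: displacement integral of a negative raised-cosine velocity bell
  u <- (t[ix] - t_close) / approach_s
  d[ix] <- open_mm - A * (u - sin(2 * pi * u) / (2 * pi))
  d[t >= t_hold & t < t1] <- closed_mm
  ix <- t >= t1 & t < t_open_end
  u <- (t[ix] - t1) / release_s           # in [0, 2)
  d[ix] <- closed_mm + (A / 2) * (u - sin(pi * u) / pi)
  d[t >= t_open_end] <- open_mm
  list(d = d, t1 = t1, t2 = t1 + release_s, t_open_end = t_open_end,
       t_close = t_close, t_hold = t_hold)
}

#' Synthesize articulator trajectories for one utterance
#'
#' The critical channel (`lio` for bilabial, `ttu` for dental plans) executes
#' closure, hold and a release whose opening-velocity profile is a raised
#' cosine: velocity is zero with positive acceleration at `truth_t1_s` and
#' peaks (zero acceleration) at `truth_t2_s`. The non-critical channel is a
#' landmark-free low-pass-filtered gaussian walk. Per-speaker articulator
#' scale and timing jitter are applied; medial-position plans get a longer
#' voiced lead-in.
#'
#' @param plan one row of [plan_corpus()] (or an equivalent list).
#' @param profile a [make_speaker()] profile.
#' @param cfg a [mi_config()] list.
#' @return list with `lio`, `ttu` (mm, at `cfg$fs_motor`), `truth_t1_s`,
#'   `truth_t2_s`, `timing` (internal landmark times) and `fs_motor`.
#' @export
synth_trajectory <- function(plan, profile, cfg = mi_config()) {
  sc <- cfg$synth
  fs <- cfg$fs_motor
  cls <- consonant_class(plan$consonant)
  crit <- critical_channel(cls)
  with_seed(derive_seed(plan$seed, "trajectory"), {
    lead_s <- stats::runif(1, sc$lead_ms_range[1], sc$lead_ms_range[2]) / 1000
    if (plan$position == "medial") lead_s <- lead_s + 0.08
    hold_s <- max(sc$hold_ms_range[1],
                  min(sc$hold_ms_range[2],
                      stats::rnorm(1, profile$hold_ms$mean, profile$hold_ms$jitter))) / 1000
    release_s <- max(sc$release_ms_range[1],
                     min(sc$release_ms_range[2],
                         stats::rnorm(1, profile$release_ms$mean, profile$release_ms$jitter))) / 1000
    approach_s <- sc$approach_ms / 1000
    # quantize gesture phases to the motor frame so landmark times fall on
    # motor samples (the 5 ms frame is below articulatory timing precision)
    q <- function(x) round(x * fs) / fs
    lead_s <- q(lead_s); hold_s <- q(hold_s)
    release_s <- q(release_s); approach_s <- q(approach_s)
    total_s <- lead_s + approach_s + hold_s + 2 * release_s +
      (sc$vowel_ms + sc$tail_ms) / 1000
    n <- ceiling(total_s * fs) + 1
    t <- (seq_len(n) - 1) / fs

    open_crit <- sc$open_mm[[crit]] * profile$articulator_scale[[crit]]
    pl <- plosion_distance(t, lead_s, approach_s, hold_s, release_s,
                           open_crit, sc$closed_mm)

    # non-critical articulator: slow postural drift (band-limited below
    # noncrit_cutoff_hz), smooth and free of plosion-like landmarks
    noncrit <- setdiff(c("lio", "ttu"), crit)
    base <- 0.6 * sc$open_mm[[noncrit]] * profile$articulator_scale[[noncrit]]
    freqs <- stats::runif(3, 0.1, sc$noncrit_cutoff_hz)
    phases <- stats::runif(3, 0, 2 * pi)
    amps <- c(1, 0.6, 0.3)
    sm <- rowSums(sapply(1:3, function(k) amps[k] * sin(2 * pi * freqs[k] * t + phases[k])))
    sm <- (sm - mean(sm)) / max(stats::sd(sm), 1e-9) * sc$noncrit_sd_mm
    d_noncrit <- pmax(0.05, base + sm)

    out <- list(truth_t1_s = pl$t1, truth_t2_s = pl$t2,
                timing = list(lead_s = lead_s, approach_s = approach_s,
                              hold_s = hold_s, release_s = release_s,
                              t_close = pl$t_close, t_hold = pl$t_hold,
                              t_open_end = pl$t_open_end, total_s = total_s),
                fs_motor = fs)
    out[[crit]] <- pl$d
    out[[noncrit]] <- d_noncrit
    out[c("lio", "ttu", "truth_t1_s", "truth_t2_s", "timing", "fs_motor")]
  })
}

# formant-tone following phone (sum of three sines with pitch-rate AM);
# with a locus, formants glide exponentially from the consonant's locus to
# the vowel target (the place-of-articulation transition cue)
formant_tone <- function(t, formants, amp, pitch_hz, locus = NULL,
                         tau = 0.025) {
  w <- c(0.5, 0.35, 0.15)
  s <- numeric(length(t))
  dt <- if (length(t) > 1) t[2] - t[1] else 0
  for (k in 1:3) {
    if (!is.null(locus) && is.finite(locus[k])) {
      f_inst <- formants[k] + (locus[k] - formants[k]) * exp(-t / tau)
      phase <- 2 * pi * cumsum(f_inst) * dt
    } else {
      phase <- 2 * pi * formants[k] * t
    }
    s <- s + w[k] * sin(phase)
  }
  amp * s * (1 + 0.25 * sin(2 * pi * pitch_hz * t)) / 1.25
}

raised_cos_ramp <- function(n_ramp, n_total) {
  env <- rep(1, n_total)
  if (n_ramp > 0 && n_total >= 2 * n_ramp) {
    r <- (1 - cos(pi * seq_len(n_ramp) / n_ramp)) / 2
    env[seq_len(n_ramp)] <- r
    env[n_total - seq_len(n_ramp) + 1] <- r
  }
  env
}

bandpass_noise <- function(n, lo_hz, hi_hz, fs) {
  x <- stats::rnorm(n + 200)
  lo <- max(lo_hz, 30) / (fs / 2)
  hi <- min(hi_hz, 0.98 * fs / 2) / (fs / 2)
  bf <- signal::butter(2, c(lo, hi), type = "pass")
  y <- signal::filtfilt(bf, x)[101:(100 + n)]
  y / max(stats::sd(y), 1e-12)
}

#' Synthesize the audio waveform for one utterance
#'
#' Deterministic given `(plan, profile, traj)`: silence (plus a faint
#' low-frequency voicing bar for the voiced consonants /b/ and /d/) during
#' closure; a release burst of band-passed noise whose envelope follows the
#' critical channel's opening velocity and whose center frequency is low for
#' bilabials and high for dentals, modulated by speaker scale and by the
#' coarticulating phone's F2 locus; then a following phone (formant tone for
#' vowels and /r/, high-band noise for /s/). Medial-position plans carry a
#' preceding vowel during the lead-in. A small recording noise floor is
#' always present.
#'
#' @param plan,profile,cfg as in [synth_trajectory()].
#' @param traj output of [synth_trajectory()].
#' @return numeric waveform at `cfg$fs_audio` Hz, spanning the same time as
#'   the motor trajectories.
#' @export
synth_audio <- function(plan, profile, traj, cfg = mi_config()) {
  sc <- cfg$synth
  fs <- cfg$fs_audio
  fsm <- cfg$fs_motor
  cls <- consonant_class(plan$consonant)
  crit <- critical_channel(cls)
  d <- traj[[crit]]
  n_a <- round(length(d) / fsm * fs)
  t <- (seq_len(n_a) - 1) / fs

  with_seed(derive_seed(plan$seed, "audio"), {
    wave <- sc$floor_amp * stats::rnorm(n_a)

    # voicing bar during closure for voiced consonants
    if (plan$consonant %in% c("b", "d")) {
      ix <- t >= traj$timing$t_hold & t < traj$truth_t1_s
      wave[ix] <- wave[ix] + sc$voicing_amp * sin(2 * pi * profile$pitch_hz * t[ix])
    }

    # release burst: envelope = critical-channel opening velocity (upsampled)
    v <- central_diff(d, fsm)
    env_m <- pmax(v, 0)
    vmax <- max(env_m)
    if (vmax > 0) {
      env <- stats::approx(x = (seq_along(d) - 1) / fsm, y = env_m / vmax,
                           xout = t, rule = 2)$y
      # burst resonance: inversely tied to vocal-tract size (articulator
      # scale, base F2), shifted by anticipatory coarticulation toward the
      # following phone's F2 locus, with token-level aerodynamic jitter
      spk_fac <- (1 / mean(profile$articulator_scale)) *
        (1750 / profile$base_formants_hz[2])
      coart_fac <- (PHONE_F2[[plan$coart_phone]] / 1400)^0.45
      tok_fac <- exp(stats::rnorm(1, 0, sc$burst_token_sd))
      centroid <- sc$burst_centroid_hz[[cls]] * spk_fac * coart_fac * tok_fac
      burst <- bandpass_noise(n_a, 0.55 * centroid, 1.6 * centroid, fs)
      wave <- wave + sc$burst_amp * env * burst
    }

    # aperture of the critical articulator (0 closed .. 1 open) at audio rate:
    # radiated vowel energy is gated by mouth/constriction opening
    open_mm <- max(d)
    aperture <- stats::approx(x = (seq_along(d) - 1) / fsm,
                              y = pmin(1, pmax(0, (d - min(d)) / (open_mm - min(d)))),
                              xout = t, rule = 2)$y

    # following phone: onsets at release + voice-onset time (short for the
    # voiced members, long for the voiceless), gated by the aperture
    vot_s <- if (plan$consonant %in% c("b", "d")) 0.010 else 0.035
    t_on <- traj$truth_t1_s + vot_s
    t_off <- traj$timing$t_open_end + sc$vowel_ms / 1000
    ix <- which(t >= t_on & t < t_off)
    if (length(ix) > 20) {
      tt <- t[ix] - t_on
      ramp <- raised_cos_ramp(round(0.02 * fs), length(ix))
      ph <- plan$coart_phone
      if (ph == "s") {
        seg <- 0.6 * sc$vowel_amp * bandpass_noise(length(ix), 4500, 7800, fs)
      } else {
        fmt <- 0.5 * (profile$base_formants_hz + PHONE_FORMANTS[[ph]])
        seg <- formant_tone(tt, fmt, sc$vowel_amp, profile$pitch_hz,
                            locus = sc$formant_locus_hz[[cls]])
      }
      wave[ix] <- wave[ix] + ramp * aperture[ix] * seg
    }

    # preceding vowel for medial position (consonant inside a word), faded
    # out by the closing aperture
    if (plan$position == "medial") {
      ix <- which(t < traj$timing$t_hold)
      if (length(ix) > 20) {
        ramp <- raised_cos_ramp(round(0.02 * fs), length(ix))
        seg <- formant_tone(t[ix], profile$base_formants_hz,
                            0.8 * sc$vowel_amp, profile$pitch_hz)
        wave[ix] <- wave[ix] + ramp * aperture[ix] * seg
      }
    }
    pmax(-1, pmin(1, wave))
  })
}

#' Synthesize one complete utterance
#'
#' @inheritParams synth_trajectory
#' @return a `synthetic_utterance` list: `audio`, `lio`, `ttu`, `truth_t1_s`,
#'   `truth_t2_s`, `plan`, `fs_audio`, `fs_motor`, `timing`.
#' @export
synth_utterance <- function(plan, profile, cfg = mi_config()) {
  traj <- synth_trajectory(plan, profile, cfg)
  audio <- synth_audio(plan, profile, traj, cfg)
  structure(list(
    audio = audio, lio = traj$lio, ttu = traj$ttu,
    truth_t1_s = traj$truth_t1_s, truth_t2_s = traj$truth_t2_s,
    plan = plan, fs_audio = cfg$fs_audio, fs_motor = cfg$fs_motor,
    timing = traj$timing
  ), class = "synthetic_utterance")
}

#' Generate a full synthetic corpus
#'
#' @param n_speakers,per_cell design size (see [plan_corpus()]).
#' @param seed master seed: profiles, plans and every utterance derive their
#'   own substream from it, so the corpus is a pure function of
#'   `(config, seed)`.
#' @param cfg a [mi_config()] list.
#' @return a `motorinv_corpus` list: `utterances` (list of
#'   [synth_utterance()] results), `manifest` (data.frame with utterance_id,
#'   speaker, consonant, class, coart_phone, position, truth_t1_s,
#'   truth_t2_s), `speakers`, `seed`, `config`.
#' @export
make_corpus <- function(n_speakers, per_cell, seed, cfg = mi_config()) {
  speakers <- lapply(seq_len(n_speakers), function(i) {
    make_speaker(derive_seed(seed, "speaker", i), cfg = cfg)
  })
  plans <- plan_corpus(n_speakers, per_cell, seed)
  utts <- lapply(seq_len(nrow(plans)), function(i) {
    plan <- as.list(plans[i, ])
    synth_utterance(plan, speakers[[plan$speaker_idx]], cfg)
  })
  manifest <- data.frame(
    utterance_id = sprintf("u%04d", seq_len(nrow(plans))),
    speaker = vapply(speakers, function(s) s$speaker_id, character(1))[plans$speaker_idx],
    consonant = plans$consonant,
    class = plans$class,
    coart_phone = plans$coart_phone,
    position = plans$position,
    truth_t1_s = vapply(utts, function(u) u$truth_t1_s, numeric(1)),
    truth_t2_s = vapply(utts, function(u) u$truth_t2_s, numeric(1)),
    stringsAsFactors = FALSE
  )
  names(utts) <- manifest$utterance_id
  structure(list(utterances = utts, manifest = manifest, speakers = speakers,
                 seed = seed, config = cfg),
            class = "motorinv_corpus")
}

#' @export
print.motorinv_corpus <- function(x, ...) {
  cat("Synthetic plosive corpus:", nrow(x$manifest), "utterances,",
      length(x$speakers), "speakers\n")
  if (nrow(x$manifest) > 0) {
    cat("classes:", sum(x$manifest$class == "bilabial"), "bilabial /",
        sum(x$manifest$class == "dental"), "dental;",
        "fs:", x$config$fs_audio, "Hz audio,", x$config$fs_motor, "Hz motor\n")
  }
  invisible(x)
}

#' Add seeded white noise to a waveform
#'
#' Gaussian noise with standard deviation `level` times the standard
#' deviation of the input waveform, the noise protocol of the robustness
#' experiment. `level = 0` returns the input unchanged (bit-identical).
#'
#' @param wave numeric waveform.
#' @param level non-negative noise level (fraction of the waveform's sd).
#' @param seed integer seed for the noise realization.
#' @return noisy waveform.
#' @export
add_white_noise <- function(wave, level, seed) {
  if (!is.numeric(level) || length(level) != 1 || level < 0) {
    stop("noise level must be a single non-negative number")
  }
  if (level == 0) return(wave)
  with_seed(seed, wave + stats::rnorm(length(wave), 0, level * stats::sd(wave)))
}
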