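#' @title The Audio-Motor Map
#'
#' @description
#' The audio-motor map (AMM) reconstructs articulator kinematics from audio
#' alone: a feed-forward network with one hidden layer of logistic-sigmoid
#' units (and sigmoid outputs) regresses each motor sample of
#' (vlio, alio, vttu, attu) from a sliding spectrogram context — the
#' concatenation of `context_slices` log-Mel slices centered on the slice
#' nearest the motor sample's time. Targets are affinely normalized into the
#' open sigmoid range; raw log-Mel inputs are fed without per-sample
#' normalization to preserve the time structure of the context. Training
#' minimizes a regularized mean-square error
#' (`reg_ratio * MSE + (1 - reg_ratio) * mean(w^2)`) with early stopping on a
#' validation set drawn from training-side utterances, repeated over random
#' restarts; the restart with the best average validation loss over the four
#' outputs is kept.
#'
#' @name amm
NULL

#' Concatenate spectrogram slices into per-motor-sample context vectors
#'
#' For each motor sample time, the `context_slices` rows centered on the
#' slice nearest that time are concatenated ((context-1)/2 preceding,
#' (context-1)/2 following); indices beyond either edge use replication
#' padding. Output dimension is `context_slices * n_mel`.
#'
#' @param slices matrix from [mel_spectrogram()] (must carry
#'   `slice_times_s`).
#' @param motor_times_s times (s) of the motor samples, in the audio's time
#'   frame.
#' @param context_slices odd context size.
#' @return `length(motor_times_s) x (context_slices * ncol(slices))` matrix.
#' @export
build_context <- function(slices, motor_times_s, context_slices = 19) {
  if (context_slices %% 2 != 1) stop("context_slices must be odd")
  st <- attr(slices, "slice_times_s")
  if (is.null(st)) stop("slices must carry the slice_times_s attribute")
  n_sl <- nrow(slices)
  half <- (context_slices - 1) / 2
  nearest <- vapply(motor_times_s, function(tm) which.min(abs(st - tm)), integer(1))
  out <- matrix(0, length(motor_times_s), context_slices * ncol(slices))
  for (i in seq_along(nearest)) {
    idx <- pmin(pmax(nearest[i] + (-half:half), 1L), n_sl)
    out[i, ] <- as.numeric(t(slices[idx, , drop = FALSE]))
  }
  out
}

#' Affine target normalization into the sigmoid range
#'
#' Maps each channel's training minimum to `range[1]` and maximum to
#' `range[2]` (the logistic output's asymptotes are 0 and 1, so targets must
#' lie strictly inside). Parameters are stored so the map inverts exactly;
#' test values outside the training range map outside `(lo, hi)`, which is
#' allowed.
#'
#' @param targets `n x k` matrix of motor samples.
#' @param range `(lo, hi)` with `0 < lo < hi < 1`.
#' @return list `scaled` (matrix), `offset`, `scale` (per channel), `range`.
#' @export
normalize_targets <- function(targets, range = c(0.1, 0.9)) {
  targets <- as.matrix(targets)
  mins <- apply(targets, 2, min)
  maxs <- apply(targets, 2, max)
  if (any(maxs - mins <= 0)) stop("constant target channel cannot be normalized")
  scale <- (range[2] - range[1]) / (maxs - mins)
  offset <- range[1] - mins * scale
  scaled <- sweep(sweep(targets, 2, scale, `*`), 2, offset, `+`)
  list(scaled = scaled, offset = offset, scale = scale, range = range)
}

#' Invert the target normalization
#'
#' @param scaled matrix in normalized units.
#' @param norm parameters from [normalize_targets()].
#' @return matrix in physical units.
#' @export
denormalize_targets <- function(scaled, norm) {
  sweep(sweep(as.matrix(scaled), 2, norm$offset, `-`), 2, norm$scale, `/`)
}

# forward pass of a one-hidden-layer sigmoid network in nnet's weight layout:
# for each hidden unit (bias, inputs...), then for each output (bias, hidden...)
mlp_forward <- function(wts, x, n_in, n_hidden, n_out) {
  x <- rbind(x)
  w1 <- matrix(wts[seq_len((n_in + 1) * n_hidden)], nrow = n_in + 1)
  w2 <- matrix(wts[(n_in + 1) * n_hidden + seq_len((n_hidden + 1) * n_out)],
               nrow = n_hidden + 1)
  h <- 1 / (1 + exp(-(cbind(1, x) %*% w1)))
  1 / (1 + exp(-(cbind(1, h) %*% w2)))
}

reg_loss <- function(pred, target, wts, reg_ratio) {
  reg_ratio * mean((pred - target)^2) + (1 - reg_ratio) * mean(wts^2)
}

# cheap row-disjointness audit between two design matrices
assert_disjoint_rows <- function(a, b, what) {
  w <- sin(seq_len(ncol(a)) * 1.2345)
  ka <- round(as.numeric(a %*% w), 9)
  kb <- round(as.numeric(b %*% w), 9)
  if (length(intersect(ka, kb)) > 0) {
    stop("validation set overlaps the training set (", what, ")")
  }
}

#' Train the audio-motor map
#'
#' Runs `cfg$restarts` seeded restarts of a one-hidden-layer
#' logistic-sigmoid network (backend: \pkg{nnet}, whose weight-decay
#' least-squares objective equals the regularized loss up to a positive
#' constant; the decay is derived from `reg_ratio`). Each restart trains in
#' warm-started chunks of `cfg$epochs_per_check` epochs; after each chunk the
#' regularized loss on the validation set is checked, and training stops when
#' it has not improved for `cfg$early_stop_patience` consecutive checks (or
#' after `cfg$max_checks` chunks). The best-validation checkpoint of the best
#' restart is returned.
#'
#' @param contexts `n x D` training contexts (raw log-Mel values).
#' @param targets `n x 4` training targets (vlio, alio, vttu, attu, physical
#'   units).
#' @param val_contexts,val_targets validation data, drawn from training-side
#'   utterances disjoint from the training rows (audited).
#' @param cfg the `amm` group of [mi_config()].
#' @param seed integer seed for restart initializations.
#' @return an `amm_model`: `wts`, layer sizes, `norm` (target
#'   normalization), `config`, `training_log` (one row per restart x check),
#'   `restart_val_losses`, `val_loss`.
#' @export
train_amm <- function(contexts, targets, val_contexts, val_targets,
                      cfg = mi_config()$amm, seed = 0) {
  contexts <- as.matrix(contexts); targets <- as.matrix(targets)
  val_contexts <- as.matrix(val_contexts); val_targets <- as.matrix(val_targets)
  stopifnot(nrow(contexts) == nrow(targets), nrow(val_contexts) == nrow(val_targets))
  assert_disjoint_rows(contexts, val_contexts, "context rows")

  if (is.finite(cfg$max_train_samples) && nrow(contexts) > cfg$max_train_samples) {
    keep <- unique(round(seq(1, nrow(contexts), length.out = cfg$max_train_samples)))
    contexts <- contexts[keep, , drop = FALSE]
    targets <- targets[keep, , drop = FALSE]
  }

  norm <- normalize_targets(targets, cfg$target_range)
  yv <- sweep(sweep(val_targets, 2, norm$scale, `*`), 2, norm$offset, `+`)
  n_in <- ncol(contexts); n_hidden <- cfg$hidden_units; n_out <- ncol(targets)
  n_w <- (n_in + 1) * n_hidden + (n_hidden + 1) * n_out
  decay <- (1 - cfg$reg_ratio) / cfg$reg_ratio *
    (nrow(contexts) * n_out) / n_w

  log_rows <- list()
  best <- list(loss = Inf, wts = NULL, restart = NA)
  restart_losses <- numeric(cfg$restarts)
  for (r in seq_len(cfg$restarts)) {
    wts <- with_seed(derive_seed(seed, "amm_restart", r),
                     stats::runif(n_w, -0.5, 0.5) / sqrt(n_in + 1))
    r_best <- Inf; r_best_wts <- wts; stall <- 0
    for (chk in seq_len(cfg$max_checks)) {
      fit <- nnet::nnet(x = contexts, y = norm$scaled, size = n_hidden,
                        Wts = wts, linout = FALSE, decay = decay,
                        maxit = cfg$epochs_per_check, trace = FALSE,
                        MaxNWts = n_w + 1, reltol = 1e-12, abstol = -1)
      wts <- fit$wts
      pv <- mlp_forward(wts, val_contexts, n_in, n_hidden, n_out)
      vl <- reg_loss(pv, yv, wts, cfg$reg_ratio)
      log_rows[[length(log_rows) + 1]] <- data.frame(
        restart = r, check = chk, epochs = chk * cfg$epochs_per_check,
        val_loss = vl
      )
      if (vl < r_best) { r_best <- vl; r_best_wts <- wts; stall <- 0 }
      else stall <- stall + 1
      if (stall >= cfg$early_stop_patience) break
    }
    restart_losses[r] <- r_best
    if (r_best < best$loss) best <- list(loss = r_best, wts = r_best_wts, restart = r)
  }
  structure(list(
    wts = best$wts, n_in = n_in, n_hidden = n_hidden, n_out = n_out,
    norm = norm, config = cfg, seed = seed,
    training_log = do.call(rbind, log_rows),
    restart_val_losses = restart_losses,
    val_loss = best$loss, best_restart = best$restart,
    channel_names = colnames(targets)
  ), class = "amm_model")
}

#' @export
print.amm_model <- function(x, ...) {
  cat("Audio-Motor Map:", x$n_in, "->", x$n_hidden, "->", x$n_out,
      "(logistic sigmoid)\n")
  cat("restarts:", length(x$restart_val_losses),
      " best validation loss:", signif(x$val_loss, 4),
      "(restart", x$best_restart, ")\n")
  invisible(x)
}

#' Reconstruct motor kinematics from audio
#'
#' Forward pass of a trained AMM on the sliding spectrogram contexts of
#' `wave`, followed by denormalization to physical units. Deterministic given
#' `(model, wave, motor_times_s)`.
#'
#' @param model an [train_amm()] result.
#' @param wave waveform.
#' @param motor_times_s times (s) of the motor samples to reconstruct.
#' @param fs_audio audio sampling rate (Hz).
#' @param cfg optional config; if supplied it must match the model's stored
#'   extraction settings.
#' @return `length(motor_times_s) x 4` matrix in physical units.
#' @export
reconstruct_motor <- function(model, wave, motor_times_s, fs_audio,
                              cfg = NULL) {
  stopifnot(inherits(model, "amm_model"))
  if (!is.null(cfg)) {
    keys <- c("win_ms", "hop_ms", "n_mel", "band_hz", "context_slices")
    if (!identical(model$config[keys], cfg[keys])) {
      stop("extraction config does not match the model's stored config")
    }
  }
  ctx <- amm_contexts(wave, motor_times_s, fs_audio, model$config)
  if (ncol(ctx) != model$n_in) {
    stop("context dimension ", ncol(ctx), " does not match model input ", model$n_in)
  }
  pred <- mlp_forward(model$wts, ctx, model$n_in, model$n_hidden, model$n_out)
  out <- denormalize_targets(pred, model$norm)
  colnames(out) <- model$channel_names
  out
}

# segment audio -> contexts at the segment's motor sample times; pads with
# zeros up to one analysis window for segments at the minimum duration
amm_contexts <- function(wave, motor_times_s, fs_audio, acfg) {
  win <- round(acfg$win_ms / 1000 * fs_audio)
  if (length(wave) < win) wave <- c(wave, numeric(win - length(wave)))
  sl <- mel_spectrogram(wave, fs_audio, acfg$win_ms, acfg$hop_ms,
                        acfg$n_mel, acfg$band_hz)
  build_context(sl, motor_times_s, acfg$context_slices)
}

#' Normalized root-mean-square error
#'
#' RMSE divided by the range of the testing targets (per the evaluation
#' convention: normalization is over the range of each testing data set).
#'
#' @param pred,truth equal-length numeric vectors.
#' @param norm_range positive scalar, `max(truth_set) - min(truth_set)` of
#'   the testing data the pair belongs to.
#' @return non-negative scalar.
#' @export
nrmse <- function(pred, truth, norm_range) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (!(is.numeric(norm_range) && norm_range > 0)) stop("norm_range must be > 0")
  sqrt(mean((pred - truth)^2)) / norm_range
}

#' Double-dissociation analysis of reconstruction quality
#'
#' For every segment, the Pearson correlation between the AMM-reconstructed
#' and the real trajectory is computed per channel; correlations are grouped
#' by plosive class and contrasted with two-sample two-tailed t-tests:
#' `r(vlio | bilabial)` vs `r(vlio | dental)` and `r(vttu | dental)` vs
#' `r(vttu | bilabial)` (likewise alio / attu). A double dissociation
#' appears when each articulator's channel is reconstructed better from the
#' consonants that constrain it.
#'
#' Segments where either trajectory is constant (undefined correlation) are
#' excluded and counted.
#'
#' @param recon,real lists of `n_i x 4` matrices (columns vlio, alio, vttu,
#'   attu), one per segment.
#' @param classes character vector (`"bilabial"`/`"dental"`) per segment.
#' @return a `reconstruction_report`: `per_segment` (data.frame of r values),
#'   `group_means`, `tests` (channel, favored class, t, df, p, degenerate
#'   flag), `n_excluded`.
#' @export
dissociation_analysis <- function(recon, real, classes) {
  stopifnot(length(recon) == length(real), length(classes) == length(recon))
  if (min(table(factor(classes, levels = c("bilabial", "dental")))) < 2) {
    stop("need at least 2 segments per class")
  }
  channels <- c("vlio", "alio", "vttu", "attu")
  rows <- list(); n_excl <- 0
  for (i in seq_along(recon)) {
    r_i <- rep(NA_real_, 4)
    ok <- TRUE
    for (k in 1:4) {
      x <- real[[i]][, k]; y <- recon[[i]][, k]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) { ok <- FALSE; break }
      r_i[k] <- stats::cor(x, y)
    }
    if (!ok) { n_excl <- n_excl + 1; next }
    rows[[length(rows) + 1]] <-
      data.frame(segment = i, class = classes[i],
                 vlio = r_i[1], alio = r_i[2], vttu = r_i[3], attu = r_i[4])
  }
  per_seg <- do.call(rbind, rows)
  gm <- stats::aggregate(per_seg[, channels], by = list(class = per_seg$class), mean)
  favored <- c(vlio = "bilabial", alio = "bilabial", vttu = "dental", attu = "dental")
  tests <- lapply(channels, function(ch) {
    x <- per_seg[per_seg$class == favored[[ch]], ch]
    y <- per_seg[per_seg$class != favored[[ch]], ch]
    tt <- tryCatch(stats::t.test(x, y, alternative = "two.sided",
                                 var.equal = TRUE),
                   error = function(e) NULL)  # zero-variance contrast
    if (is.null(tt)) {
      data.frame(channel = ch, favored = favored[[ch]],
                 mean_favored = mean(x), mean_other = mean(y),
                 t = NA_real_, df = NA_real_, p = NA_real_, degenerate = TRUE)
    } else {
      data.frame(channel = ch, favored = favored[[ch]],
                 mean_favored = mean(x), mean_other = mean(y),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, degenerate = FALSE)
    }
  })
  structure(list(per_segment = per_seg, group_means = gm,
                 tests = do.call(rbind, tests), n_excluded = n_excl),
            class = "reconstruction_report")
}
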