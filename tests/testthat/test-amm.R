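test_that("the log-Mel spectrogram has the documented slice geometry", {
  fs <- 16000
  w <- sin(2 * pi * 440 * seq(0, 1, by = 1 / fs))[1:fs]
  sl <- mel_spectrogram(w, fs, win_ms = 20, hop_ms = 10, n_mel = 24)
  expect_equal(nrow(sl), 99)   # floor((1000 - 20) / 10) + 1
  expect_equal(ncol(sl), 24)

  tone <- sin(2 * pi * 1000 * seq(0, 0.5, by = 1 / fs))
  sl <- mel_spectrogram(tone, fs, n_mel = 24, band_hz = c(100, 8000))
  centers <- attr(sl, "centers_hz")
  expect_equal(unname(which.max(sl[10, ])), which.min(abs(centers - 1000)))

  silent <- mel_spectrogram(numeric(8000), fs)
  expect_true(all(apply(silent, 2, function(col) all(col == col[1]))))

  expect_error(mel_spectrogram(numeric(100), fs), "shorter")
})

test_that("context vectors concatenate and pad as documented", {
  sl <- matrix(rnorm(20 * 24), 20, 24)
  attr(sl, "slice_times_s") <- seq(0.01, by = 0.01, length.out = 20)

  ctx1 <- build_context(sl, c(0.052), context_slices = 1)
  expect_equal(as.numeric(ctx1), as.numeric(sl[5, ]))

  ctx19 <- build_context(sl, c(0.1, 0.15), context_slices = 19)
  expect_equal(dim(ctx19), c(2, 19 * 24))

  # a motor time at the very start: leading blocks replicate row 1
  ctx <- build_context(sl, 0, context_slices = 5)
  expect_equal(ctx[1, 1:24], ctx[1, 25:48])
  expect_equal(as.numeric(ctx[1, 1:24]), as.numeric(sl[1, ]))

  expect_error(build_context(sl, 0.1, context_slices = 4), "odd")
})

test_that("target normalization is an exact invertible affine map", {
  y <- cbind(c(-3, 7, 2), c(0, 10, 5))
  nr <- normalize_targets(y, range = c(0.1, 0.9))
  expect_equal(nr$scaled[, 1], c(0.1, 0.9, 0.5))
  expect_equal(denormalize_targets(nr$scaled, nr), y, tolerance = 1e-12)

  set.seed(2)
  y2 <- matrix(rnorm(200), 50, 4)
  nr2 <- normalize_targets(y2)
  expect_equal(denormalize_targets(nr2$scaled, nr2), y2, tolerance = 1e-12)
  # values outside the training range map outside (lo, hi) -- allowed
  out <- sweep(sweep(matrix(100, 1, 4), 2, nr2$scale, `*`), 2, nr2$offset, `+`)
  expect_true(all(out > 0.9))

  expect_error(normalize_targets(cbind(rep(1, 5), 1:5)), "constant")
})

toy_amm_data <- function(n = 260, d = 6, seed = 5) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  W <- matrix(runif(d * 4, -0.5, 0.5), d, 4)
  Y <- X %*% W
  list(X = X, Y = Y)
}

test_that("training learns a linear toy mapping and honors its contracts", {
  toy <- toy_amm_data()
  tr <- 1:200; va <- 201:260
  cfg <- test_config()$amm
  cfg$hidden_units <- 10
  cfg$restarts <- 3
  cfg$reg_ratio <- 0.999     # near-pure MSE so the least-squares bound applies
  cfg$epochs_per_check <- 60
  cfg$max_checks <- 12
  cfg$early_stop_patience <- 3
  m <- train_amm(toy$X[tr, ], toy$Y[tr, ], toy$X[va, ], toy$Y[va, ], cfg, seed = 3)

  # final training MSE (normalized scale) well under the target variance --
  # an exact linear map exists, so the least-squares bound is ~zero
  pred <- motorinv:::mlp_forward(m$wts, toy$X[tr, ], m$n_in, m$n_hidden, m$n_out)
  yn <- sweep(sweep(toy$Y[tr, ], 2, m$norm$scale, `*`), 2, m$norm$offset, `+`)
  expect_lt(mean((pred - yn)^2), 0.1 * mean(apply(yn, 2, var)))

  # determinism and restart bookkeeping
  m2 <- train_amm(toy$X[tr, ], toy$Y[tr, ], toy$X[va, ], toy$Y[va, ], cfg, seed = 3)
  expect_identical(m$wts, m2$wts)
  expect_equal(length(m$restart_val_losses), 3)
  expect_equal(max(table(m$training_log$restart) > 0), 1)
  expect_equal(m$val_loss, min(m$restart_val_losses))

  # the best-so-far validation record never worsens within a restart
  for (r in unique(m$training_log$restart)) {
    vl <- m$training_log$val_loss[m$training_log$restart == r]
    expect_true(all(diff(cummin(vl)) <= 0))
  }

  # validation rows overlapping training rows are refused
  expect_error(
    train_amm(toy$X[tr, ], toy$Y[tr, ], toy$X[c(1, 201:210), ],
              toy$Y[c(1, 201:210), ], cfg, seed = 3),
    "overlaps")
})

test_that("reconstruction from audio is deterministic with correct shape", {
  toy <- toy_amm_data()
  cfg <- test_config()$amm
  cfg$hidden_units <- 6; cfg$restarts <- 1; cfg$max_checks <- 3
  # a real model trained on segment audio from the small corpus
  corpus <- small_corpus()
  segs <- small_segments()
  al <- align_segments(corpus, segs[1:30, ], corpus$config)
  sd_ <- motorinv:::amm_segment_data(al, cfg)
  ctx <- do.call(rbind, lapply(sd_[1:25], `[[`, "contexts"))
  tgt <- do.call(rbind, lapply(sd_[1:25], `[[`, "targets"))
  vctx <- do.call(rbind, lapply(sd_[26:30], `[[`, "contexts"))
  vtgt <- do.call(rbind, lapply(sd_[26:30], `[[`, "targets"))
  m <- train_amm(ctx, tgt, vctx, vtgt, cfg, seed = 1)

  seg <- al[[1]]
  times <- (seg$motor_idx - seg$motor_idx[1]) / seg$fs_motor
  r1 <- reconstruct_motor(m, seg$audio, times, seg$fs_audio)
  expect_equal(nrow(r1), length(times))
  expect_equal(ncol(r1), 4)
  expect_identical(r1, reconstruct_motor(m, seg$audio, times, seg$fs_audio))

  bad_cfg <- cfg; bad_cfg$n_mel <- cfg$n_mel + 4
  expect_error(reconstruct_motor(m, seg$audio, times, seg$fs_audio, cfg = bad_cfg),
               "does not match")

  # reconstructing the training inputs of a converged toy model correlates
  # strongly with the targets
  toy_cfg <- cfg; toy_cfg$hidden_units <- 8; toy_cfg$max_checks <- 8
  tm <- train_amm(toy$X[1:200, ], toy$Y[1:200, ], toy$X[201:260, ],
                  toy$Y[201:260, ], toy_cfg, seed = 2)
  pred <- denormalize_targets(
    motorinv:::mlp_forward(tm$wts, toy$X[1:200, ], tm$n_in, tm$n_hidden, tm$n_out),
    tm$norm)
  for (k in 1:4) expect_gt(cor(pred[, k], toy$Y[1:200, k]), 0.9)
})

test_that("NRMSE matches its closed form and rejects degenerate ranges", {
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3), 2), 0)
  expect_equal(nrmse(c(1, 0), c(0, 1), 1), 1)

  set.seed(8)
  for (i in 1:100) {
    p <- rnorm(20); t <- rnorm(20); rng <- runif(1, 0.5, 3)
    expect_equal(nrmse(p, t, rng), sqrt(mean((p - t)^2)) / rng,
                 tolerance = 1e-12)
  }
  expect_error(nrmse(1:3, 1:3, 0), "norm_range")
  expect_error(nrmse(1:3, 1:4, 1), "lengths")

  # the trivial mean predictor attains population-sd / range
  x <- rnorm(50)
  expect_equal(nrmse(rep(mean(x), 50), x, diff(range(x))),
               sqrt(mean((x - mean(x))^2)) / diff(range(x)), tolerance = 1e-12)
})

test_that("per-segment correlations and dissociation tests match oracles", {
  set.seed(9)
  # correlation against the covariance-formula oracle
  for (i in 1:100) {
    x <- rnorm(50); y <- rnorm(50)
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(cor(x, y), r_oracle, tolerance = 1e-10)
  }

  # perfect reconstruction: all r = 1, zero-variance contrasts are degenerate
  segs <- lapply(1:6, function(i) matrix(rnorm(40), 10, 4))
  rep_perfect <- dissociation_analysis(segs, segs,
                                       rep(c("bilabial", "dental"), 3))
  expect_true(all(abs(as.matrix(rep_perfect$per_segment[, 3:6]) - 1) < 1e-12))
  expect_true(all(rep_perfect$tests$degenerate))

  # constant trajectories are excluded and counted
  segs2 <- segs
  segs2[[2]][, 1] <- 0
  rep2 <- dissociation_analysis(segs2, segs2, rep(c("bilabial", "dental"), 3))
  expect_equal(rep2$n_excluded, 1)
  expect_equal(nrow(rep2$per_segment), 5)

  expect_error(dissociation_analysis(segs[1:2], segs[1:2],
                                     c("bilabial", "bilabial")),
               "2 segments per class")

  # t statistic against the pooled-variance textbook formula
  set.seed(10)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  sp <- sqrt(((11) * var(a) + (14) * var(b)) / (12 + 15 - 2))
  t_oracle <- (mean(a) - mean(b)) / (sp * sqrt(1 / 12 + 1 / 15))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(unname(tt$statistic), t_oracle, tolerance = 1e-10)
})
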