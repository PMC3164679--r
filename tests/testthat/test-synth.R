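test_that("speaker profiles are deterministic, seed-sensitive and validated", {
  p1 <- make_speaker(1)
  p2 <- make_speaker(1)
  expect_identical(p1, p2)

  # over 100 seed pairs the draw collides with negligible probability: each
  # profile holds 8 independent continuous draws
  diffs <- vapply(1:100, function(s) {
    a <- make_speaker(s); b <- make_speaker(s + 1000)
    !identical(a$articulator_scale, b$articulator_scale) ||
      !identical(a$pitch_hz, b$pitch_hz)
  }, logical(1))
  expect_true(all(diffs))

  expect_error(make_speaker(1, list(articulator_scale = c(lio = -1, ttu = 1))),
               "articulator_scale")
  expect_error(make_speaker(1, list(base_formants_hz = c(500, 400, 3000))),
               "formants")
  expect_error(make_speaker(1, list(nope = 1)), "unknown profile field")
})

test_that("corpus plans form an exactly balanced design", {
  plans <- plan_corpus(6, 1, seed = 0)
  expect_equal(nrow(plans), 336)  # 6 * 4 * 7 * 2
  expect_true(all(table(plans$consonant, plans$coart_phone) > 0))

  plans2 <- plan_corpus(1, 2, seed = 0)
  expect_equal(nrow(plans2), 112)
  cells <- table(plans2$consonant, plans2$coart_phone, plans2$position)
  expect_true(all(cells == 2))

  expect_equal(sum(plans$class == "bilabial"), sum(plans$class == "dental"))
})

test_that("trajectories realize the plosion landmarks by construction", {
  cfg <- test_config()
  fs <- cfg$fs_motor
  for (s in 1:25) {
    plan <- list(speaker_idx = 1, consonant = "b", class = "bilabial",
                 coart_phone = "a", position = "initial", seed = s)
    prof <- make_speaker(s, cfg = cfg)
    tr <- synth_trajectory(plan, prof, cfg)
    v <- motorinv:::central_diff(tr$lio, fs)
    i1 <- round(tr$truth_t1_s * fs) + 1
    # opening onset: null velocity (central differences), positive acceleration
    expect_lt(abs(v[i1]), 0.01 * max(v))
    a <- motorinv:::central_diff(v, fs)
    expect_gt(a[i1], 0)
    # velocity peak at truth_t2 within one motor sample (brute-force argmax)
    rel <- which.max(v)
    expect_lte(abs((rel - 1) / fs - tr$truth_t2_s), 1 / fs)
    # the critical channel closes to near zero before t1
    expect_lt(min(tr$lio[1:i1]), 1)
  }
})

test_that("the non-critical channel rarely shows duration-qualifying plosions", {
  cfg <- test_config()
  kc <- cfg$kinematics
  n_with_candidate <- 0
  for (s in 1:200) {
    plan <- list(speaker_idx = 1, consonant = "d", class = "dental",
                 coart_phone = "o", position = "initial", seed = s)
    prof <- make_speaker(s %% 7, cfg = cfg)
    tr <- synth_trajectory(plan, prof, cfg)
    kin <- smooth_and_differentiate(
      motor_channel("lio", tr$lio, cfg$fs_motor), kc$smoothing_window)
    cand <- detect_plosions(kin, kc$min_dur_ms, kc$max_dur_ms)
    if (nrow(cand) > 0) n_with_candidate <- n_with_candidate + 1
  }
  expect_lte(n_with_candidate / 200, 0.10)
})

test_that("audio synthesis is deterministic and class-shaped", {
  cfg <- test_config()
  prof <- make_speaker(3, cfg = cfg)
  mk <- function(cons, cls) {
    plan <- list(speaker_idx = 1, consonant = cons, class = cls,
                 coart_phone = "e", position = "initial", seed = 99)
    tr <- synth_trajectory(plan, prof, cfg)
    list(plan = plan, tr = tr, wave = synth_audio(plan, prof, tr, cfg))
  }
  b <- mk("b", "bilabial")
  b2 <- synth_audio(b$plan, prof, b$tr, cfg)
  expect_identical(b$wave, b2)

  d <- mk("d", "dental")
  win <- function(u) {
    fs <- cfg$fs_audio
    i1 <- round(u$tr$truth_t1_s * fs); i2 <- round(u$tr$truth_t2_s * fs)
    u$wave[(i1 + 1):i2]
  }
  # burst spectral centroid lower for the bilabial release
  expect_lt(spectral_centroid(win(b), cfg$fs_audio),
            spectral_centroid(win(d), cfg$fs_audio))

  # closure is silent relative to the release
  t <- (seq_along(b$wave) - 1) / cfg$fs_audio
  cl <- t >= b$tr$timing$t_hold & t < b$tr$truth_t1_s
  rl <- t >= b$tr$truth_t1_s & t < b$tr$timing$t_open_end
  expect_lt(sqrt(mean(b$wave[cl]^2)) / sqrt(mean(b$wave[rl]^2)), 0.05)
})

test_that("white-noise injection honors level and seeding contracts", {
  w <- sin(2 * pi * 5 * seq(0, 1, by = 1 / 16000))
  expect_identical(add_white_noise(w, 0, 1), w)

  n1 <- add_white_noise(w, 1, 11) - w
  n2 <- add_white_noise(w, 1, 12) - w
  expect_equal(sd(n1) / sd(w), 1, tolerance = 0.05)
  expect_equal(sd(n2) / sd(w), 1, tolerance = 0.05)
  expect_false(identical(n1, n2))
  expect_error(add_white_noise(w, -0.1, 1), "non-negative")
})

test_that("corpus generation is a pure function of (config, seed)", {
  cfg <- test_config()
  c1 <- make_corpus(1, 1, seed = 5, cfg)
  c2 <- make_corpus(1, 1, seed = 5, cfg)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$utterances[[10]]$audio, c2$utterances[[10]]$audio)
  expect_identical(c1$utterances[[10]]$lio, c2$utterances[[10]]$lio)
  # class balance is exact
  expect_equal(sum(c1$manifest$class == "bilabial"),
               sum(c1$manifest$class == "dental"))
})

test_that("ground-truth landmarks satisfy the plosion definition corpus-wide", {
  # landmark validity on clean trajectories, checked by central differences
  cfg <- test_config()
  fs <- cfg$fs_motor
  corpus <- cached("landmark_corpus", make_corpus(5, 2, seed = 123, cfg))
  n_checked <- 0
  for (id in corpus$manifest$utterance_id) {
    utt <- corpus$utterances[[id]]
    crit <- critical_channel(consonant_class(utt$plan$consonant))
    d <- utt[[crit]]
    v <- motorinv:::central_diff(d, fs)
    a <- motorinv:::central_diff(v, fs)
    i1 <- round(utt$truth_t1_s * fs) + 1
    i2 <- round(utt$truth_t2_s * fs) + 1
    expect_lt(abs(v[i1]), 0.01 * max(v))
    expect_gt(a[i1], 0)
    expect_lt(abs(a[i2]), 0.02 * max(abs(a)))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 560)
})
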