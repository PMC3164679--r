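test_that("sensor distances match the elementwise Euclidean oracle", {
  n <- 100
  s1 <- matrix(0, n, 3)
  expect_true(all(euclidean_distance(s1, s1, 200)$d == 0))

  s2 <- matrix(rep(c(3, 4, 0), each = n), n, 3)
  expect_equal(euclidean_distance(s1, s2, 200)$d, rep(5, n))

  set.seed(31)
  a <- matrix(rnorm(3 * n), n, 3); b <- matrix(rnorm(3 * n), n, 3)
  oracle <- sapply(seq_len(n), function(i) sqrt(sum((a[i, ] - b[i, ])^2)))
  expect_equal(euclidean_distance(a, b, 200)$d, oracle, tolerance = 1e-12)

  expect_error(euclidean_distance(a, b[1:50, ], 200), "equal dimensions")
})

test_that("smoothing and differentiation follow calculus on known signals", {
  fs <- 200
  const <- motor_channel("lio", rep(4.2, 100), fs)
  k <- smooth_and_differentiate(const, 5)
  expect_true(all(k$v == 0) && all(k$a == 0))

  ramp <- motor_channel("lio", 0.3 * (0:99) / fs, fs)
  k <- smooth_and_differentiate(ramp, 5)
  interior <- 6:94
  expect_equal(k$v[interior], rep(0.3, length(interior)), tolerance = 1e-9)
  expect_equal(k$a[interior], rep(0, length(interior)), tolerance = 1e-6)

  # analytic derivative of a 2 Hz sinusoid, no smoothing
  t <- (0:199) / fs
  ch <- motor_channel("ttu", sin(2 * pi * 2 * t), fs)
  k <- smooth_and_differentiate(ch, 1)
  v_true <- 2 * pi * 2 * cos(2 * pi * 2 * t)
  interior <- 10:190
  expect_lt(max(abs(k$v[interior] - v_true[interior])) / max(abs(k$v)), 0.01)

  expect_error(smooth_and_differentiate(const, 4), "odd")
})

test_that("plosion detection locates the synthetic ground truth", {
  cfg <- test_config()
  kc <- cfg$kinematics
  flat <- smooth_and_differentiate(motor_channel("lio", rep(1, 80), 200), 3)
  expect_equal(nrow(detect_plosions(flat, kc$min_dur_ms, kc$max_dur_ms)), 0)

  hits <- 0
  for (s in 1:50) {
    cons <- c("b", "t")[s %% 2 + 1]
    cls <- consonant_class(cons)
    plan <- list(speaker_idx = 1, consonant = cons, class = cls,
                 coart_phone = "a", position = "initial", seed = 4000 + s)
    prof <- make_speaker(s, cfg = cfg)
    tr <- synth_trajectory(plan, prof, cfg)
    crit <- critical_channel(cls)
    kin <- smooth_and_differentiate(
      motor_channel(crit, tr[[crit]], cfg$fs_motor), kc$smoothing_window)
    cand <- detect_plosions(kin, kc$min_dur_ms, kc$max_dur_ms)
    expect_equal(nrow(cand), 1)
    expect_lte(abs(cand$t1_s - tr$truth_t1_s) * cfg$fs_motor, 2 + 1e-9)
    expect_lte(abs(cand$t2_s - tr$truth_t2_s) * cfg$fs_motor, 2 + 1e-9)
    hits <- hits + 1
  }
  expect_equal(hits, 50)
})

test_that("every returned candidate satisfies the sign conditions (brute force)", {
  # non-critical smooth-noise channels can produce candidates; each one must
  # still satisfy the kinematic definition when re-checked on the raw arrays
  cfg <- test_config()
  n_cand <- 0
  for (s in 1:40) {
    plan <- list(speaker_idx = 1, consonant = "d", class = "dental",
                 coart_phone = "u", position = "medial", seed = 7000 + s)
    prof <- make_speaker(s, cfg = cfg)
    tr <- synth_trajectory(plan, prof, cfg)
    kin <- smooth_and_differentiate(motor_channel("lio", tr$lio, cfg$fs_motor), 3)
    cand <- detect_plosions(kin, 0, 1e6)   # no duration filter
    for (i in seq_len(nrow(cand))) {
      i1 <- cand$t1_idx[i] + 1; i2 <- cand$t2_idx[i] + 1
      # upward v crossing around t1 with positive acceleration
      expect_true(any(kin$v[max(1, i1 - 1):i1] <= 0))
      expect_true(any(kin$v[i1:(i1 + 1)] > 0))
      expect_gt(max(kin$a[max(1, i1 - 1):(i1 + 1)]), 0)
      # downward a crossing around t2
      expect_true(any(kin$a[max(1, i2 - 1):i2] > 0))
      expect_true(any(kin$a[i2:min(length(kin$a), i2 + 1)] <= 0))
      n_cand <- n_cand + 1
    }
  }
  expect_gt(n_cand, 0)  # the brute-force check must actually have run
})

test_that("vetting accepts by two-sided overlap and attaches labels", {
  cand <- data.frame(channel = "lio", t1_idx = 20L, t2_idx = 28L,
                     t1_s = 0.10, t2_s = 0.14, stringsAsFactors = FALSE)
  truth <- data.frame(t1_s = 0.10, t2_s = 0.14, channel = "lio",
                      consonant = "b", class = "bilabial", speaker = "spk1",
                      coart_phone = "a", stringsAsFactors = FALSE)
  acc <- vet_segments(cand, truth = truth)
  expect_equal(nrow(acc), 1)
  expect_equal(acc$class, "bilabial")
  expect_equal(acc$coart_phone, "a")

  # disjoint and sub-threshold overlaps are rejected
  expect_equal(nrow(vet_segments(cand, truth = transform(truth, t1_s = 0.5, t2_s = 0.54))), 0)
  # candidate [0.10, 0.14] vs truth [0.124, 0.164]: 40% mutual overlap
  expect_equal(nrow(vet_segments(cand, truth = transform(truth, t1_s = 0.124, t2_s = 0.164))), 0)

  expect_error(vet_segments(cand, truth = truth, accept_fn = function(x) TRUE),
               "at most one")
  acc2 <- vet_segments(cand, accept_fn = function(x) x$channel == "lio")
  expect_equal(nrow(acc2), 1)
})

test_that("segment extraction is exact, closed-interval and repeatable", {
  corpus <- small_corpus()
  segs <- small_segments()
  seg <- segs[1, ]
  utt <- corpus$utterances[[seg$utterance_id]]
  al <- extract_segment(utt, seg)
  # closed motor interval [t1, t2] includes both landmark samples
  expect_equal(nrow(al$kin), seg$t2_idx - seg$t1_idx + 1)
  expect_equal(ncol(al$kin), 4)
  expect_equal(length(al$audio),
               round((seg$t2_s - seg$t1_s) * utt$fs_audio))
  al2 <- extract_segment(utt, seg)
  expect_identical(al, al2)

  bad <- seg; bad$t2_idx <- length(utt$lio) + 5
  expect_error(extract_segment(utt, bad), "out of bounds")
})

test_that("cross-channel vetting accepts zero wrong-channel segments", {
  segs <- small_segments()
  expect_true(all(segs$channel == critical_channel(segs$class)))
  # and per-utterance recall on the critical channel is complete here
  expect_equal(sort(unique(segs$utterance_id)),
               sort(small_corpus()$manifest$utterance_id))
})
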