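test_that("schema split counts follow the combinatorics of 6 speakers / 5 vowels", {
  segs <- fake_segment_table(6)
  counts <- c(spk5vs1 = 6, spk3vs3 = 20, spk1vs5 = 6,
              coart4vs1 = 5, coart3vs2 = 10)
  for (sch in names(counts)) {
    sp <- make_splits(segs, sch, seed = 1)
    expect_length(sp, unname(counts[sch]))
    for (s in sp) expect_true(audit_split(s, segs))
  }
  # spk5vs1: every test side is a single speaker
  for (s in make_splits(segs, "spk5vs1", seed = 1)) {
    expect_length(unique(segs$speaker[match(s$test, segs$utterance_id)]), 1)
  }
})

test_that("the overall schema forms k equal random folds, each tested once", {
  segs <- fake_segment_table(6)
  sp <- make_splits(segs, "overall", k = 6, seed = 3)
  test_sizes <- vapply(sp, function(s) length(s$test), integer(1))
  expect_true(max(test_sizes) - min(test_sizes) <= 1)
  all_tested <- sort(unlist(lapply(sp, `[[`, "test")))
  expect_equal(all_tested, sort(segs$utterance_id))

  # deterministic under the seed
  sp2 <- make_splits(segs, "overall", k = 6, seed = 3)
  expect_identical(lapply(sp, `[[`, "test"), lapply(sp2, `[[`, "test"))

  expect_error(make_splits(segs[1:4, ], "overall", k = 10, seed = 1), "exceeds")
})

test_that("/r/ and /s/ never reach a coarticulation training side", {
  segs <- fake_segment_table(6)
  for (sch in c("coart4vs1", "coart3vs2")) {
    for (s in make_splits(segs, sch, seed = 2)) {
      tr_phones <- unique(segs$coart_phone[match(s$train, segs$utterance_id)])
      expect_false(any(c("r", "s") %in% tr_phones))
      te_phones <- unique(segs$coart_phone[match(s$test, segs$utterance_id)])
      expect_true(all(c("r", "s") %in% te_phones))
    }
  }
})

test_that("the split audit catches violated invariants", {
  segs <- fake_segment_table(6)
  sp <- make_splits(segs, "spk5vs1", seed = 1)[[1]]
  bad <- sp
  bad$train <- c(bad$train, bad$test[1])
  expect_error(audit_split(bad, segs), "overlap")
  bad2 <- sp
  bad2$amm_validation <- c(bad2$amm_validation, sp$test[1])
  expect_error(audit_split(bad2, segs), "validation")
  bad3 <- sp
  bad3$test <- bad3$test[-1]
  bad3$train <- c(bad3$train, sp$test[1])
  expect_error(audit_split(bad3, segs), "speaker")
})

test_that("the AMM validation set is a stratified subset of the training side", {
  segs <- fake_segment_table(6)
  for (s in make_splits(segs, "overall", k = 4, seed = 5, val_frac = 0.1)) {
    expect_true(all(s$amm_validation %in% s$train))
    val_cls <- segs$class[match(s$amm_validation, segs$utterance_id)]
    expect_setequal(unique(val_cls), c("bilabial", "dental"))
    expect_equal(length(s$amm_validation), round(0.1 * length(s$train)),
                 tolerance = 2)
  }
})

test_that("pairwise comparisons behave on degenerate and symmetric input", {
  ps <- data.frame(
    schema = "overall", split_id = rep(1:4, 2), level = 0,
    feature_set = rep(c("audio", "real"), each = 4),
    balanced_error = c(0.2, 0.3, 0.25, 0.22, 0.2, 0.3, 0.25, 0.22)
  )
  res <- structure(list(per_split = ps), class = "experiment_result")
  tab <- compare_feature_sets(res)
  expect_equal(tab$p, 1)  # identical error vectors

  ps$balanced_error[5:8] <- c(0.05, 0.02, 0.08, 0.04)
  res$per_split <- ps
  tab <- compare_feature_sets(res)
  # swapping the sets flips the t sign, same p
  ps_sw <- ps
  ps_sw$feature_set <- rep(c("real", "audio"), each = 4)
  ps_sw$balanced_error <- c(ps$balanced_error[5:8], ps$balanced_error[1:4])
  tab_sw <- compare_feature_sets(structure(list(per_split = ps_sw),
                                           class = "experiment_result"))
  expect_equal(tab$t, -tab_sw$t, tolerance = 1e-12)
  expect_equal(tab$p, tab_sw$p, tolerance = 1e-12)

  # t statistic against the pooled-variance formula
  a <- ps$balanced_error[1:4]; b <- ps$balanced_error[5:8]
  sp_ <- sqrt((3 * var(a) + 3 * var(b)) / 6)
  expect_equal(tab$t, (mean(a) - mean(b)) / (sp_ * sqrt(0.5)), tolerance = 1e-10)
})

test_that("discrimination runs end-to-end and label shuffling hits chance", {
  corpus <- small_corpus()
  segs <- small_segments()
  splits <- make_splits(segs, "overall", k = 4, seed = 11)
  r <- run_discrimination(corpus, segs, splits[1:2], c("audio", "real"),
                          corpus$config, seed = 11)
  expect_equal(nrow(r$per_split), 4)
  expect_true(all(r$per_split$balanced_error >= 0 &
                  r$per_split$balanced_error <= 1))
  # real motor separates the classes on the clean corpus
  expect_lt(mean(r$per_split$balanced_error[r$per_split$feature_set == "real"]),
            0.05)

  # permutation null: shuffled labels put every set near chance
  segs_perm <- segs
  with_seed(99, {
    perm <- sample(nrow(segs_perm))
    segs_perm$class <- segs_perm$class[perm]
    segs_perm$consonant <- segs_perm$consonant[perm]
  })
  splits_p <- make_splits(segs_perm, "overall", k = 4, seed = 12)
  rp <- run_discrimination(corpus, segs_perm, splits_p[1:2], c("real"),
                           corpus$config, seed = 12)
  bers <- rp$per_split$balanced_error
  expect_true(all(bers > 0.35 & bers < 0.65))
})

test_that("experiment reruns with identical config and seed are identical", {
  corpus <- small_corpus()
  segs <- small_segments()
  splits <- make_splits(segs, "spk1vs5", seed = 4)
  r1 <- run_discrimination(corpus, segs, splits[1], c("audio", "real"),
                           corpus$config, seed = 4)
  r2 <- run_discrimination(corpus, segs, splits[1], c("audio", "real"),
                           corpus$config, seed = 4)
  expect_identical(r1$per_split, r2$per_split)
})
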