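clouds <- function(n = 100, sep = 4, d = 6, seed = 77) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * d), n, d),
             matrix(rnorm(n * d, mean = sep / sqrt(d)), n, d))
  list(x = x, y = rep(c("bilabial", "dental"), each = n))
}

test_that("feature normalization uses training statistics only", {
  set.seed(41)
  tr <- matrix(rnorm(200, mean = 3, sd = 2), 20, 10)
  te <- matrix(rnorm(100, mean = -1, sd = 0.5), 10, 10)
  nm <- normalize_features(tr, te, "zscore")
  expect_equal(colMeans(nm$train), rep(0, 10), tolerance = 1e-10)
  expect_equal(apply(nm$train, 2, sd), rep(1, 10), tolerance = 1e-10)
  # test statistics differ because train statistics were applied
  expect_false(any(abs(colMeans(nm$test)) < 1e-6))

  pass <- normalize_features(tr, te, "none")
  expect_identical(pass$train, tr)
  expect_identical(pass$test, te)

  # zero-variance dimensions are dropped and recorded
  tr2 <- cbind(tr, 5)
  nm2 <- normalize_features(tr2, cbind(te, 5), "zscore")
  expect_equal(nm2$stats$dropped, 11)
  expect_equal(ncol(nm2$train), 10)

  expect_error(normalize_features(tr[0, ], NULL, "zscore"), "empty")
})

test_that("balanced error rate follows its definition", {
  tr <- rep(c("bilabial", "dental"), each = 10)
  expect_equal(balanced_error_rate(tr, tr), 0)

  pred <- tr
  pred[1:2] <- "dental"   # 8/10 bilabials correct
  pred[11:14] <- "bilabial"  # 6/10 dentals correct
  expect_equal(balanced_error_rate(pred, tr), 0.3)

  expect_equal(balanced_error_rate(rep("bilabial", 20), tr), 0.5)
  expect_error(balanced_error_rate(tr, rep("bilabial", 20)), "both classes")
})

test_that("a label-permutation predictor sits at chance", {
  set.seed(43)
  tr <- rep(c("bilabial", "dental"), times = c(30, 26))
  bers <- replicate(1000, balanced_error_rate(sample(tr), tr))
  sem <- sd(bers) / sqrt(1000)
  expect_lt(abs(mean(bers) - 0.5), 3 * sem + 1e-8)
})

test_that("grid-searched SVMs separate gaussian clouds and are deterministic", {
  cl <- clouds()
  m <- train_svm(cl$x, cl$y, cost_grid = c(1, 100),
                 gamma_grid = c(0.01, 0.1), inner_folds = 5, seed = 1)
  pred <- predict(m, cl$x)
  expect_lt(balanced_error_rate(pred$label, cl$y), 0.05)

  m2 <- train_svm(cl$x, cl$y, cost_grid = c(1, 100),
                  gamma_grid = c(0.01, 0.1), inner_folds = 5, seed = 1)
  expect_equal(c(m$cost, m$gamma), c(m2$cost, m2$gamma))
  expect_identical(predict(m, cl$x), predict(m2, cl$x))

  m3 <- train_svm(cl$x, cl$y, cost_grid = 10, gamma_grid = 0.05,
                  inner_folds = 3, seed = 1)
  expect_equal(m3$cost, 10)
  expect_equal(m3$gamma, 0.05)

  expect_error(train_svm(cl$x[1:100, ], cl$y[1:100]), "both classes")
})

test_that("posteriors are calibrated probabilities with a fixed tie rule", {
  cl <- clouds()
  m <- train_svm(cl$x, cl$y, cost_grid = 1, gamma_grid = 0.05, seed = 2)
  pred <- predict(m, cl$x)
  expect_true(all(pred$p_bilabial >= 0 & pred$p_bilabial <= 1))
  # a deep bilabial-side point gets a bilabial-side posterior
  deep <- matrix(rep(c(-2, colMeans(cl$x[1:100, -1])), 1), 1)
  deep <- cl$x[which.min(rowSums(cl$x)), , drop = FALSE]
  expect_gt(predict(m, deep)$p_bilabial, 0.5)

  expect_error(predict(m, cl$x[, 1:3]), "dimension")
})

test_that("joint decisions average posteriors with ties to dental", {
  pa <- data.frame(utterance_id = c("a", "b", "c"),
                   p_bilabial = c(0.9, 0.6, 0.2),
                   label = c("bilabial", "bilabial", "dental"))
  pm <- data.frame(utterance_id = c("a", "b", "c"),
                   p_bilabial = c(0.9, 0.4, 0.1),
                   label = c("bilabial", "dental", "dental"))
  j <- joint_decision(pa, pm)
  expect_equal(j$p_bilabial, c(0.9, 0.5, 0.15))
  expect_equal(j$label, c("bilabial", "dental", "dental"))  # 0.5 tie -> dental

  # symmetric and idempotent
  expect_equal(joint_decision(pm, pa)$p_bilabial, j$p_bilabial)
  jj <- joint_decision(pa, pa)
  expect_equal(jj$p_bilabial, pa$p_bilabial)

  pm2 <- pm; pm2$utterance_id <- c("a", "b", "x")
  expect_error(joint_decision(pa, pm2), "different utterances")
})

test_that("no test-side information leaks into training decisions", {
  # recompute the normalization and the grid selection from the training
  # split alone and confirm the fitted model used exactly those
  cl <- clouds(n = 60)
  tr_ix <- c(1:40, 61:100)
  te_ix <- setdiff(seq_len(120), tr_ix)
  nm <- normalize_features(cl$x[tr_ix, ], cl$x[te_ix, ], "zscore")
  m <- train_svm(nm$train, cl$y[tr_ix], cost_grid = c(1, 100),
                 gamma_grid = c(0.01, 0.1), inner_folds = 4, seed = 9)
  nm_only_train <- normalize_features(cl$x[tr_ix, ], NULL, "zscore")
  expect_identical(nm$stats$mean, nm_only_train$stats$mean)
  m_again <- train_svm(nm_only_train$train, cl$y[tr_ix],
                       cost_grid = c(1, 100), gamma_grid = c(0.01, 0.1),
                       inner_folds = 4, seed = 9)
  expect_equal(c(m$cost, m$gamma), c(m_again$cost, m_again$gamma))
})
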