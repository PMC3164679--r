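#' @title Bilabial-vs-dental classification
#'
#' @description
#' Binary classifiers over any of the feature encodings: a support vector
#' machine with Gaussian (RBF) kernel, hyperparameters `(C, gamma)` found by
#' grid search minimizing inner-cross-validated balanced error on the
#' training split. Motor feature sets are z-scored dimension-wise with
#' training statistics; audio features are used raw (the feature-set
#' normalization policy). Posterior probabilities are approximate: a Platt
#' sigmoid fitted on cross-validated decision values. The *joint* decision
#' averages the audio and reconstructed-motor posteriors and thresholds at
#' 0.5 (ties to dental).
#'
#' @name classify
NULL

CLASS_LEVELS <- c("bilabial", "dental")

#' Feature normalization with training statistics only
#'
#' `mode = "zscore"` subtracts per-dimension training means and divides by
#' training standard deviations (applied identically to the test matrix, so
#' no test-side information leaks); zero-variance training dimensions are
#' dropped and recorded. `mode = "none"` passes both matrices through
#' unchanged.
#'
#' @param train,test numeric matrices with matching columns (`test` may be
#'   `NULL`).
#' @param mode `"zscore"` or `"none"`.
#' @return list `train`, `test`, `stats` (`mean`, `sd`, `kept` column
#'   indices, `dropped`).
#' @export
normalize_features <- function(train, test = NULL, mode = c("zscore", "none")) {
  mode <- match.arg(mode)
  train <- as.matrix(train)
  if (nrow(train) == 0) stop("empty training matrix")
  if (mode == "none") {
    return(list(train = train, test = test, stats = list(mode = "none")))
  }
  mu <- colMeans(train)
  sd_ <- apply(train, 2, stats::sd)
  kept <- which(sd_ > 0)
  if (length(kept) == 0) stop("all training dimensions have zero variance")
  ztr <- sweep(sweep(train[, kept, drop = FALSE], 2, mu[kept]), 2, sd_[kept], `/`)
  zte <- if (is.null(test)) NULL else {
    sweep(sweep(as.matrix(test)[, kept, drop = FALSE], 2, mu[kept]), 2, sd_[kept], `/`)
  }
  list(train = ztr, test = zte,
       stats = list(mode = "zscore", mean = mu, sd = sd_, kept = kept,
                    dropped = setdiff(seq_len(ncol(train)), kept)))
}

#' Balanced error rate
#'
#' One minus the mean of the per-class recalls (the average of the ratios of
#' correctly predicted bilabials and dentals), which unlike plain accuracy
#' rewards getting *both* classes right. A constant predictor scores exactly
#' 0.5.
#'
#' @param preds predicted labels.
#' @param truths true labels; both classes must be present.
#' @return scalar in `[0, 1]`.
#' @export
balanced_error_rate <- function(preds, truths) {
  truths <- as.character(truths); preds <- as.character(preds)
  if (!all(CLASS_LEVELS %in% truths)) {
    stop("both classes must be present in the truth labels")
  }
  recalls <- vapply(CLASS_LEVELS, function(cl) {
    mean(preds[truths == cl] == cl)
  }, numeric(1))
  1 - mean(recalls)
}

# stratified fold assignment, seeded and deterministic
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      ix <- which(y == cl)
      ix <- ix[sample.int(length(ix))]
      fold[ix] <- rep_len(seq_len(k), length(ix))
    }
  })
  fold
}

# Platt scaling: fit sigmoid p = 1 / (1 + exp(A*f + B)) by regularized
# maximum likelihood (Newton with backtracking, per Lin/Weng/Keerthi)
platt_fit <- function(f, positive) {
  prior1 <- sum(positive); prior0 <- sum(!positive)
  hi <- (prior1 + 1) / (prior1 + 2); lo <- 1 / (prior0 + 2)
  t <- ifelse(positive, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  fval <- function(A, B) {
    z <- A * f + B
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  fv <- fval(A, B)
  for (it in 1:100) {
    z <- A * f + B
    p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    d1 <- t - p
    d2 <- p * (1 - p)
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-10 && abs(g2) < 1e-10) break
    h11 <- sum(f * f * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    step <- 1
    repeat {
      A2 <- A + step * dA; B2 <- B + step * dB
      f2 <- fval(A2, B2)
      if (f2 < fv + 1e-4 * step * (g1 * dA + g2 * dB) || step < 1e-10) break
      step <- step / 2
    }
    A <- A + step * dA; B <- B + step * dB
    fv <- fval(A, B)
  }
  c(A = A, B = B)
}

svm_decision <- function(fit, x) {
  pr <- stats::predict(fit, x, decision.values = TRUE)
  dvm <- attr(pr, "decision.values")
  dv <- as.numeric(dvm)
  # orient so a positive decision value means "bilabial"
  if (grepl("^dental", colnames(dvm)[1])) dv <- -dv
  dv
}

#' Train an RBF-kernel SVM with grid search and calibrated posteriors
#'
#' Selects `(C, gamma)` by `inner_folds`-fold stratified cross-validation on
#' the training split, minimizing balanced error (ties resolved toward the
#' first grid entry, smallest cost then smallest gamma); refits on the full
#' training split; fits a Platt sigmoid on cross-validated decision values of
#' the selected configuration. Deterministic given `(x, y, grid, seed)`.
#'
#' @param x numeric feature matrix (already normalized per the feature-set
#'   policy).
#' @param y labels (`"bilabial"` / `"dental"`); both classes required.
#' @param cost_grid,gamma_grid positive hyperparameter grids.
#' @param inner_folds inner CV fold count.
#' @param seed integer seed for fold assignment.
#' @return an `mi_svm` model: `fit` (e1071 svm), `platt`, selection metadata.
#' @export
train_svm <- function(x, y, cost_grid = 2^seq(-5, 15, 2),
                      gamma_grid = 2^seq(-15, 3, 2), inner_folds = 5,
                      seed = 0) {
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = CLASS_LEVELS)
  if (any(is.na(y))) stop("labels must be 'bilabial' or 'dental'")
  if (length(unique(y)) < 2) stop("training set must contain both classes")
  grid <- expand.grid(gamma = gamma_grid, cost = cost_grid,
                      KEEP.OUT.ATTRS = FALSE)[, c("cost", "gamma")]
  k <- min(inner_folds, min(table(y)))
  fold <- stratified_folds(as.character(y), k, derive_seed(seed, "svm_folds"))
  cv_ber <- numeric(nrow(grid))
  if (nrow(grid) > 1) {
    for (g in seq_len(nrow(grid))) {
      errs <- numeric(k)
      for (f in seq_len(k)) {
        tr <- fold != f
        fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], type = "C-classification",
                          kernel = "radial", cost = grid$cost[g],
                          gamma = grid$gamma[g], scale = FALSE)
        pr <- stats::predict(fit, x[!tr, , drop = FALSE])
        errs[f] <- if (all(CLASS_LEVELS %in% y[!tr])) {
          balanced_error_rate(as.character(pr), as.character(y[!tr]))
        } else {
          mean(as.character(pr) != as.character(y[!tr]))
        }
      }
      cv_ber[g] <- mean(errs)
    }
    sel <- which.min(cv_ber)   # first minimum in grid order
  } else sel <- 1L
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                    cost = grid$cost[sel], gamma = grid$gamma[sel], scale = FALSE)
  # cross-validated decision values for calibration
  dv <- numeric(nrow(x))
  for (f in seq_len(k)) {
    tr <- fold != f
    ff <- e1071::svm(x[tr, , drop = FALSE], y[tr], type = "C-classification",
                     kernel = "radial", cost = grid$cost[sel],
                     gamma = grid$gamma[sel], scale = FALSE)
    dv[!tr] <- svm_decision(ff, x[!tr, , drop = FALSE])
  }
  platt <- platt_fit(dv, y == "bilabial")
  structure(list(fit = fit, platt = platt, cost = grid$cost[sel],
                 gamma = grid$gamma[sel], grid = grid, cv_ber = cv_ber,
                 inner_folds = k, seed = seed, dim = ncol(x)),
            class = "mi_svm")
}

#' Predict class posteriors and labels
#'
#' @param object an `mi_svm` model.
#' @param newdata feature matrix with the training dimensionality.
#' @param ids optional utterance ids to attach.
#' @param ... unused.
#' @return data.frame: `utterance_id` (if given), `p_bilabial`, `label`
#'   (`bilabial` iff `p_bilabial > 0.5`; ties go to dental).
#' @export
predict.mi_svm <- function(object, newdata, ids = NULL, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$dim) {
    stop("feature dimension ", ncol(newdata), " does not match training (",
         object$dim, ")")
  }
  dv <- svm_decision(object$fit, newdata)
  z <- object$platt["A"] * dv + object$platt["B"]
  p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
  res <- data.frame(p_bilabial = pmin(1, pmax(0, p)),
                    label = ifelse(p > 0.5, "bilabial", "dental"),
                    stringsAsFactors = FALSE)
  if (!is.null(ids)) res <- cbind(utterance_id = ids, res, stringsAsFactors = FALSE)
  res
}

#' Fuse two posterior predictions
#'
#' Averages the posterior bilabial probabilities of two prediction tables for
#' the same utterances and thresholds at 0.5; a tie at exactly 0.5 is labeled
#' dental (a fixed, documented rule). Symmetric in its two inputs.
#'
#' @param pred_audio,pred_motor data.frames from [predict.mi_svm()] carrying
#'   `utterance_id` and `p_bilabial`.
#' @return data.frame `utterance_id`, `p_bilabial`, `label`.
#' @export
joint_decision <- function(pred_audio, pred_motor) {
  if (is.null(pred_audio$utterance_id) || is.null(pred_motor$utterance_id)) {
    stop("both predictions need utterance ids")
  }
  if (!setequal(pred_audio$utterance_id, pred_motor$utterance_id) ||
      nrow(pred_audio) != nrow(pred_motor)) {
    stop("prediction tables cover different utterances")
  }
  m <- pred_motor[match(pred_audio$utterance_id, pred_motor$utterance_id), ]
  p <- (pred_audio$p_bilabial + m$p_bilabial) / 2
  data.frame(utterance_id = pred_audio$utterance_id,
             p_bilabial = p,
             label = ifelse(p > 0.5, "bilabial", "dental"),
             stringsAsFactors = FALSE)
}
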