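#' @title Cross-validation schemas and experiments
#'
#' @description
#' Six cross-validation schemas probe the classifiers' sensitivity to the
#' sources of speech variability: `overall` (k random equal folds),
#' `spk5vs1` / `spk3vs3` / `spk1vs5` (train on m speakers, test on the
#' complement — speaker-independent evaluation), and `coart4vs1` /
#' `coart3vs2` (train on m of the five coarticulating vowels; the remaining
#' vowels plus /r/ and /s/ — never seen in training — form the test side).
#' Three experiments run on top: feature-set comparison under the overall
#' schema, under the grouped schemas, and under additive white noise.
#'
#' @name experiments
NULL

SCHEMAS <- c("overall", "spk5vs1", "spk3vs3", "spk1vs5", "coart4vs1", "coart3vs2")
COART_VOWELS <- c("a", "e", "i", "o", "u")

#' Construct cross-validation splits for a schema
#'
#' Splitting operates on utterances (each vetted segment belongs to one
#' utterance). For speaker schemas every m-subset of speakers forms one
#' training side; for coarticulation schemas every m-subset of the five
#' vowels trains and /r/, /s/ are always test-side. Each split reserves a
#' stratified fraction of its training utterances as the audio-motor-map
#' validation set for early stopping.
#'
#' @param segments labeled segment table ([segment_corpus()] output: needs
#'   `utterance_id`, `class`, `speaker`, `coart_phone`).
#' @param schema one of `r paste(SCHEMAS, collapse=", ")`.
#' @param k fold count for the `overall` schema.
#' @param seed integer seed (fold assignment, validation draw).
#' @param val_frac fraction of training utterances held out for AMM early
#'   stopping.
#' @return list of `cv_split` lists: `schema`, `split_id`, `train`, `test`,
#'   `amm_validation` (utterance-id vectors; `amm_validation` is a subset of
#'   `train`).
#' @export
make_splits <- function(segments, schema, k = 6, seed = 0, val_frac = 0.1) {
  schema <- match.arg(schema, SCHEMAS)
  ids <- segments$utterance_id
  stopifnot(!anyDuplicated(ids))
  splits <- switch(schema,
    overall = {
      if (k > length(ids)) stop("k exceeds the number of utterances")
      fold <- with_seed(derive_seed(seed, "overall_folds"),
                        sample(rep_len(seq_len(k), length(ids))))
      lapply(seq_len(k), function(f) {
        list(train = ids[fold != f], test = ids[fold == f])
      })
    },
    spk5vs1 = speaker_splits(segments, 5),
    spk3vs3 = speaker_splits(segments, 3),
    spk1vs5 = speaker_splits(segments, 1),
    coart4vs1 = coart_splits(segments, 4),
    coart3vs2 = coart_splits(segments, 3)
  )
  out <- lapply(seq_along(splits), function(i) {
    sp <- splits[[i]]
    val <- draw_validation(sp$train, segments, val_frac,
                           derive_seed(seed, "amm_val", i))
    s <- list(schema = schema, split_id = i, train = sp$train, test = sp$test,
              amm_validation = val)
    class(s) <- "cv_split"
    audit_split(s, segments)
    s
  })
  out
}

speaker_splits <- function(segments, m) {
  spk <- sort(unique(segments$speaker))
  if (length(spk) < 2) stop("speaker schemas need at least 2 speakers")
  combos <- utils::combn(spk, m, simplify = FALSE)
  lapply(combos, function(tr_spk) {
    list(train = segments$utterance_id[segments$speaker %in% tr_spk],
         test = segments$utterance_id[!segments$speaker %in% tr_spk])
  })
}

coart_splits <- function(segments, m) {
  combos <- utils::combn(COART_VOWELS, m, simplify = FALSE)
  lapply(combos, function(tr_v) {
    list(train = segments$utterance_id[segments$coart_phone %in% tr_v],
         test = segments$utterance_id[!segments$coart_phone %in% tr_v])
  })
}

draw_validation <- function(train_ids, segments, val_frac, seed) {
  cls <- segments$class[match(train_ids, segments$utterance_id)]
  with_seed(seed, {
    val <- character(0)
    for (cl in unique(cls)) {
      ix <- train_ids[cls == cl]
      n_val <- max(1, round(val_frac * length(ix)))
      val <- c(val, sample(ix, n_val))
    }
    sort(val)
  })
}

#' Audit a split's disjointness and group-exclusivity invariants
#'
#' Stops with a diagnostic if training and test sides intersect, if the AMM
#' validation set is not inside the training side, if any speaker (speaker
#' schemas) or coarticulating vowel (coart schemas) appears on both sides, or
#' if /r/ or /s/ reached a coart training side.
#'
#' @param split a `cv_split`.
#' @param segments the segment table the split was built from.
#' @return invisibly `TRUE`.
#' @export
audit_split <- function(split, segments) {
  fail <- function(...) stop("split audit [", split$schema, " #", split$split_id,
                             "]: ", ...)
  if (length(intersect(split$train, split$test)) > 0) fail("train/test overlap")
  if (!all(split$amm_validation %in% split$train)) {
    fail("AMM validation not inside training side")
  }
  grp <- function(ids, col) unique(segments[[col]][match(ids, segments$utterance_id)])
  if (startsWith(split$schema, "spk")) {
    if (length(intersect(grp(split$train, "speaker"), grp(split$test, "speaker"))) > 0) {
      fail("speaker on both sides")
    }
  }
  if (startsWith(split$schema, "coart")) {
    tr_v <- grp(split$train, "coart_phone")
    te_v <- grp(split$test, "coart_phone")
    if (length(intersect(tr_v, te_v)) > 0) fail("coart phone on both sides")
    if (any(c("r", "s") %in% tr_v)) fail("/r/ or /s/ on a training side")
  }
  invisible(TRUE)
}

# --- shared helpers -------------------------------------------------------

# per-segment AMM data: sliding contexts from the utterance waveform centered
# at the segment's motor-sample times, targets = segment kinematics
amm_segment_data <- function(aligned, acfg) {
  lapply(aligned, function(seg) {
    times <- seg$motor_idx / seg$fs_motor
    list(contexts = amm_contexts(seg$utt_audio, times, seg$fs_audio, acfg),
         targets = seg$kin)
  })
}

stack_amm <- function(sdata, ids_keep, all_ids) {
  ix <- which(all_ids %in% ids_keep)
  list(contexts = do.call(rbind, lapply(sdata[ix], `[[`, "contexts")),
       targets = do.call(rbind, lapply(sdata[ix], `[[`, "targets")))
}

fit_split_amm <- function(sdata, split, all_ids, acfg, seed) {
  fit_ids <- setdiff(split$train, split$amm_validation)
  tr <- stack_amm(sdata, fit_ids, all_ids)
  va <- stack_amm(sdata, split$amm_validation, all_ids)
  train_amm(tr$contexts, tr$targets, va$contexts, va$targets, acfg,
            seed = derive_seed(seed, "amm", split$schema, split$split_id))
}

recon_features_from_contexts <- function(model, sdata, aligned, ids_keep, all_ids) {
  ix <- which(all_ids %in% ids_keep)
  rows <- lapply(ix, function(i) {
    rec <- denormalize_targets(
      mlp_forward(model$wts, sdata[[i]]$contexts, model$n_in, model$n_hidden,
                  model$n_out), model$norm)
    colnames(rec) <- colnames(aligned[[i]]$kin)
    motor_features(aligned[[i]], "reconstructed", recon = rec)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- all_ids[ix]
  m
}

new_experiment_result <- function(per_split, extra = list()) {
  agg <- stats::aggregate(balanced_error ~ schema + feature_set + level,
                          data = per_split, FUN = function(e) {
                            c(mean = mean(e),
                              sem = stats::sd(e) / sqrt(length(e)),
                              n_splits = length(e))
                          })
  agg <- cbind(agg[, c("schema", "feature_set", "level")],
               as.data.frame(agg$balanced_error))
  structure(c(list(per_split = per_split, summary = agg), extra),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment result over", length(unique(x$per_split$split_id)), "split(s)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# fit one feature set's normalizer + SVM on a training side
fit_set <- function(xtr, ytr, mode, ccfg, seed) {
  nm <- normalize_features(xtr, NULL, mode)
  model <- train_svm(nm$train, ytr, ccfg$cost_grid, ccfg$gamma_grid,
                     ccfg$inner_folds, seed = seed)
  list(model = model, stats = nm$stats, mode = mode)
}

apply_set <- function(fs, xte, ids) {
  xte <- as.matrix(xte)
  if (fs$mode == "zscore") {
    st <- fs$stats
    xte <- sweep(sweep(xte[, st$kept, drop = FALSE], 2, st$mean[st$kept]),
                 2, st$sd[st$kept], `/`)
  }
  stats::predict(fs$model, xte, ids = ids)
}

# train + evaluate one feature set on one split; returns predictions and BER
eval_one_set <- function(xtr, ytr, xte, yte, mode, ccfg, seed, test_ids) {
  fs <- fit_set(xtr, ytr, mode, ccfg, seed)
  pred <- apply_set(fs, xte, test_ids)
  list(pred = pred, ber = balanced_error_rate(pred$label, yte), model = fs$model)
}

# --- experiments ----------------------------------------------------------

#' Run the phoneme-discrimination experiment
#'
#' For every split and requested feature set: compute features, apply the
#' feature-set normalization policy (z-score with training statistics for the
#' motor sets, none for audio), grid-search and train the SVM on the training
#' side, and measure the balanced error rate on the test side. The
#' audio-motor map behind `"reconstructed"` (and the motor half of
#' `"joint"`) is trained only on that split's training utterances, with the
#' split's held-out validation utterances driving early stopping. `"joint"`
#' averages the audio and reconstructed posteriors.
#'
#' @param corpus a [make_corpus()] corpus.
#' @param segments vetted labeled segments ([segment_corpus()]).
#' @param splits list of `cv_split`s ([make_splits()]).
#' @param feature_sets subset of `c("audio", "real", "reconstructed",
#'   "joint")`.
#' @param cfg a [mi_config()] list.
#' @param seed integer seed.
#' @return an `experiment_result`: `per_split` (schema, feature_set,
#'   split_id, level, balanced_error), `summary` (mean, SEM), `tests`
#'   (pairwise t-tests via [compare_feature_sets()]).
#' @export
run_discrimination <- function(corpus, segments,
                               splits, feature_sets = c("audio", "real"),
                               cfg = corpus$config, seed = 0) {
  if ("joint" %in% feature_sets &&
      !all(c("audio", "reconstructed") %in% feature_sets)) {
    stop("'joint' requires both 'audio' and 'reconstructed'")
  }
  all_ids <- segments$utterance_id
  aligned <- align_segments(corpus, segments, cfg)
  feats <- list()
  if ("audio" %in% feature_sets) feats$audio <- feature_matrix(aligned, "audio", cfg)
  if ("real" %in% feature_sets) feats$real <- feature_matrix(aligned, "real", cfg)
  need_amm <- any(c("reconstructed", "joint") %in% feature_sets)
  sdata <- if (need_amm) amm_segment_data(aligned, cfg$amm)
  y_all <- segments$class

  rows <- list()
  for (sp in splits) {
    audit_split(sp, segments)
    tr <- all_ids %in% sp$train
    te <- all_ids %in% sp$test
    preds <- list()
    model <- if (need_amm) fit_split_amm(sdata, sp, all_ids, cfg$amm, seed)
    if ("reconstructed" %in% feature_sets) {
      feats$reconstructed <- matrix(NA_real_, length(all_ids), 16)
      rf <- recon_features_from_contexts(model, sdata, aligned,
                                         c(sp$train, sp$test), all_ids)
      feats$reconstructed[match(rownames(rf), all_ids), ] <- rf
    }
    for (set in setdiff(feature_sets, "joint")) {
      mode <- if (set == "audio") "none" else "zscore"
      r <- eval_one_set(feats[[set]][tr, , drop = FALSE], y_all[tr],
                        feats[[set]][te, , drop = FALSE], y_all[te],
                        mode, cfg$classify,
                        derive_seed(seed, "svm", sp$schema, sp$split_id,
                                    match(set, c("audio", "real", "reconstructed"))),
                        all_ids[te])
      preds[[set]] <- r$pred
      rows[[length(rows) + 1]] <- data.frame(
        schema = sp$schema, feature_set = set, split_id = sp$split_id,
        level = 0, balanced_error = r$ber
      )
    }
    if ("joint" %in% feature_sets) {
      jp <- joint_decision(preds$audio, preds$reconstructed)
      rows[[length(rows) + 1]] <- data.frame(
        schema = sp$schema, feature_set = "joint", split_id = sp$split_id,
        level = 0, balanced_error = balanced_error_rate(jp$label, y_all[te])
      )
    }
  }
  per_split <- do.call(rbind, rows)
  res <- new_experiment_result(per_split)
  res$tests <- compare_feature_sets(res)
  res
}

#' Evaluate audio-motor-map reconstruction over splits
#'
#' Per split: train the AMM on the training side (early stopping on the
#' split's validation utterances), then on the test side compute per-channel
#' NRMSE (normalized by the test side's own target range), the closed-form
#' mean-predictor baseline (population sd / range of the test targets), and
#' per-segment real-vs-reconstructed correlations feeding the
#' double-dissociation analysis pooled over splits.
#'
#' @inheritParams run_discrimination
#' @return list: `nrmse` (data.frame schema, split_id, channel, nrmse,
#'   baseline_nrmse), `dissociation` (a `reconstruction_report` pooled over
#'   test sides), `models` (one `amm_model` per split).
#' @export
run_amm_evaluation <- function(corpus, segments, splits, cfg = corpus$config,
                               seed = 0) {
  all_ids <- segments$utterance_id
  aligned <- align_segments(corpus, segments, cfg)
  sdata <- amm_segment_data(aligned, cfg$amm)
  channels <- c("vlio", "alio", "vttu", "attu")
  nrmse_rows <- list(); models <- list()
  rec_list <- list(); real_list <- list(); cls_list <- character(0)
  for (sp in splits) {
    audit_split(sp, segments)
    model <- fit_split_amm(sdata, sp, all_ids, cfg$amm, seed)
    models[[length(models) + 1]] <- model
    te_ix <- which(all_ids %in% sp$test)
    pred <- lapply(te_ix, function(i) {
      denormalize_targets(
        mlp_forward(model$wts, sdata[[i]]$contexts, model$n_in,
                    model$n_hidden, model$n_out), model$norm)
    })
    truth <- lapply(te_ix, function(i) sdata[[i]]$targets)
    P <- do.call(rbind, pred); Tm <- do.call(rbind, truth)
    for (k in seq_along(channels)) {
      rng <- diff(range(Tm[, k]))
      sd_pop <- sqrt(mean((Tm[, k] - mean(Tm[, k]))^2))
      nrmse_rows[[length(nrmse_rows) + 1]] <- data.frame(
        schema = sp$schema, split_id = sp$split_id, channel = channels[k],
        nrmse = nrmse(P[, k], Tm[, k], rng),
        baseline_nrmse = sd_pop / rng
      )
    }
    for (j in seq_along(te_ix)) {
      rec_list[[length(rec_list) + 1]] <- pred[[j]]
      real_list[[length(real_list) + 1]] <- truth[[j]]
      cls_list <- c(cls_list, segments$class[te_ix[j]])
    }
  }
  list(nrmse = do.call(rbind, nrmse_rows),
       dissociation = dissociation_analysis(rec_list, real_list, cls_list),
       models = models)
}

#' Run the noise-robustness experiment
#'
#' Re-evaluates the feature-set comparison as white noise is added to the
#' evaluated audio: for each noise level (a multiple of each utterance's
#' waveform standard deviation) every test utterance receives `replicates`
#' seeded noisy realizations, and audio and reconstructed-motor features are
#' recomputed from the noisy audio. Classifiers and the per-split audio-motor
#' map are trained on the split's training side, which by default stays clean
#' (`noise_on_train = FALSE`, mirroring a protocol where the deployed system
#' was trained in quiet); with `noise_on_train = TRUE` the training side
#' receives one noisy realization per level and everything is retrained per
#' level. Real-motor features never touch the audio, so their errors are
#' computed once and are bit-identical across levels. Seed substreams per
#' (schema, split, feature set) match [run_discrimination()], so level 0
#' reproduces that experiment's errors exactly.
#'
#' @inheritParams run_discrimination
#' @param levels non-negative noise levels.
#' @param replicates noisy copies per test utterance.
#' @param noise_on_train whether training-side audio also receives noise.
#' @return an `experiment_result` with a `level` column in `per_split`.
#' @export
run_noise_experiment <- function(corpus, segments, splits,
                                 levels = c(0, 1, 2), replicates = 5,
                                 feature_sets = c("audio", "real",
                                                  "reconstructed", "joint"),
                                 cfg = corpus$config, seed = 0,
                                 noise_on_train = cfg$experiments$noise_on_train) {
  stopifnot(all(levels >= 0))
  all_ids <- segments$utterance_id
  aligned <- align_segments(corpus, segments, cfg)
  y_all <- segments$class
  need_audio <- any(c("audio", "joint") %in% feature_sets)
  need_amm <- any(c("reconstructed", "joint") %in% feature_sets)
  rows <- list()

  noisy_seg <- function(seg, id, lvl_i, lvl, rep_i, side) {
    # corrupt the utterance waveform, then refresh both the full-waveform
    # view (AMM contexts) and the segment's audio window (audio features)
    utt <- corpus$utterances[[id]]
    w <- add_white_noise(utt$audio, lvl,
                         derive_seed(seed, "noise", lvl_i, side,
                                     match(id, all_ids), rep_i))
    a0 <- round(seg$t1_s * seg$fs_audio) + 1
    seg$utt_audio <- w
    seg$audio <- w[a0:(a0 + length(seg$audio) - 1)]
    seg
  }
  set_seed_for <- function(sp, set) {
    derive_seed(seed, "svm", sp$schema, sp$split_id,
                match(set, c("audio", "real", "reconstructed")))
  }

  # real-motor features never touch the audio: evaluate once, reuse per level
  real_ber <- NULL
  if ("real" %in% feature_sets) {
    fr <- feature_matrix(aligned, "real", cfg)
    real_ber <- vapply(splits, function(sp) {
      tr <- all_ids %in% sp$train; te <- all_ids %in% sp$test
      eval_one_set(fr[tr, , drop = FALSE], y_all[tr], fr[te, , drop = FALSE],
                   y_all[te], "zscore", cfg$classify, set_seed_for(sp, "real"),
                   all_ids[te])$ber
    }, numeric(1))
  }

  # per-split training on one side; with clean training this happens once,
  # otherwise per level inside the loop below
  train_side <- function(sp, tr_aligned, sdata_tr) {
    out <- list()
    tr <- all_ids %in% sp$train
    if (need_audio) {
      fa <- feature_matrix(tr_aligned[tr], "audio", cfg)
      out$audio <- fit_set(fa, y_all[tr], "none", cfg$classify,
                           set_seed_for(sp, "audio"))
    }
    if (need_amm) {
      out$amm <- local({
        fit_ids <- setdiff(sp$train, sp$amm_validation)
        trd <- stack_amm(sdata_tr, fit_ids, all_ids)
        vad <- stack_amm(sdata_tr, sp$amm_validation, all_ids)
        train_amm(trd$contexts, trd$targets, vad$contexts, vad$targets,
                  cfg$amm,
                  seed = derive_seed(seed, "amm", sp$schema, sp$split_id))
      })
      xr <- recon_features_from_contexts(out$amm, sdata_tr, tr_aligned,
                                         sp$train, all_ids)
      out$rec <- fit_set(xr, y_all[match(rownames(xr), all_ids)], "zscore",
                         cfg$classify, set_seed_for(sp, "reconstructed"))
    }
    out
  }

  clean_models <- NULL
  if (!noise_on_train) {
    sdata_clean <- if (need_amm) amm_segment_data(aligned, cfg$amm)
    clean_models <- lapply(splits, train_side, tr_aligned = aligned,
                           sdata_tr = sdata_clean)
  }

  for (lvl_i in seq_along(levels)) {
    lvl <- levels[lvl_i]
    if (noise_on_train) {
      tr_aligned <- lapply(seq_along(aligned), function(i) {
        seg <- aligned[[i]]
        if (lvl > 0) seg <- noisy_seg(seg, all_ids[i], lvl_i, lvl, 0, 1)
        seg
      })
      sdata_tr <- if (need_amm) amm_segment_data(tr_aligned, cfg$amm)
      models <- lapply(splits, train_side, tr_aligned = tr_aligned,
                       sdata_tr = sdata_tr)
    } else {
      models <- clean_models
    }
    te_aligned <- lapply(seq_len(replicates), function(rp) {
      lapply(seq_along(aligned), function(i) {
        seg <- aligned[[i]]
        if (lvl > 0) seg <- noisy_seg(seg, all_ids[i], lvl_i, lvl, rp, 2)
        seg
      })
    })
    fa_te <- if (need_audio) {
      lapply(te_aligned, function(al) feature_matrix(al, "audio", cfg))
    }
    sdata_te <- if (need_amm) lapply(te_aligned, amm_segment_data, acfg = cfg$amm)

    for (si in seq_along(splits)) {
      sp <- splits[[si]]
      audit_split(sp, segments)
      te_ix <- which(all_ids %in% sp$test)
      test_inst_ids <- as.vector(vapply(seq_len(replicates), function(rp) {
        paste0(all_ids[te_ix], "_r", rp)
      }, character(length(te_ix))))
      y_te <- rep(y_all[te_ix], times = replicates)
      preds <- list()

      if (need_audio) {
        xte <- do.call(rbind, lapply(fa_te, function(m) m[te_ix, , drop = FALSE]))
        preds$audio <- apply_set(models[[si]]$audio, xte, test_inst_ids)
        if ("audio" %in% feature_sets) {
          rows[[length(rows) + 1]] <- data.frame(
            schema = sp$schema, feature_set = "audio", split_id = sp$split_id,
            level = lvl,
            balanced_error = balanced_error_rate(preds$audio$label, y_te))
        }
      }
      if (need_amm) {
        xte <- do.call(rbind, lapply(seq_len(replicates), function(rp) {
          recon_features_from_contexts(models[[si]]$amm, sdata_te[[rp]],
                                       te_aligned[[rp]], all_ids[te_ix], all_ids)
        }))
        preds$reconstructed <- apply_set(models[[si]]$rec, xte, test_inst_ids)
        if ("reconstructed" %in% feature_sets) {
          rows[[length(rows) + 1]] <- data.frame(
            schema = sp$schema, feature_set = "reconstructed",
            split_id = sp$split_id, level = lvl,
            balanced_error = balanced_error_rate(preds$reconstructed$label, y_te))
        }
        if ("joint" %in% feature_sets) {
          jp <- joint_decision(preds$audio, preds$reconstructed)
          rows[[length(rows) + 1]] <- data.frame(
            schema = sp$schema, feature_set = "joint", split_id = sp$split_id,
            level = lvl,
            balanced_error = balanced_error_rate(jp$label, y_te))
        }
      }
      if ("real" %in% feature_sets) {
        rows[[length(rows) + 1]] <- data.frame(
          schema = sp$schema, feature_set = "real", split_id = sp$split_id,
          level = lvl, balanced_error = real_ber[si])
      }
    }
  }
  per_split <- do.call(rbind, rows)
  new_experiment_result(per_split)
}

#' Pairwise feature-set comparison within schemas
#'
#' Two-sample two-tailed t-tests between the per-split balanced-error vectors
#' of every feature-set pair within each schema (and noise level), plus means
#' and standard errors. With a single split, or two error vectors with zero
#' pooled variance, the test is undefined and reported as degenerate.
#'
#' @param result an `experiment_result`.
#' @return data.frame: schema, level, set_a, set_b, mean_a, mean_b, t, df, p,
#'   degenerate.
#' @export
compare_feature_sets <- function(result) {
  ps <- result$per_split
  out <- list()
  for (sch in unique(ps$schema)) for (lvl in unique(ps$level)) {
    sub <- ps[ps$schema == sch & ps$level == lvl, ]
    sets <- unique(sub$feature_set)
    if (length(sets) < 2) next
    for (i in seq_along(sets)) for (j in seq_along(sets)) {
      if (i >= j) next
      a <- sub$balanced_error[sub$feature_set == sets[i]]
      b <- sub$balanced_error[sub$feature_set == sets[j]]
      degen <- length(a) < 2 || length(b) < 2
      tt <- if (degen) NULL else {
        tryCatch(stats::t.test(a, b, alternative = "two.sided",
                               var.equal = TRUE),
                 error = function(e) NULL)   # zero pooled variance
      }
      if (is.null(tt)) {
        degen <- TRUE
        tt <- list(statistic = NA_real_, parameter = NA_real_,
                   p.value = if (length(a) >= 2 && identical(a, b)) 1 else NA_real_)
      }
      out[[length(out) + 1]] <- data.frame(
        schema = sch, level = lvl, set_a = sets[i], set_b = sets[j],
        mean_a = mean(a), mean_b = mean(b),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value, degenerate = degen
      )
    }
  }
  if (length(out) == 0) return(data.frame())
  do.call(rbind, out)
}
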