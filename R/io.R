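#' @title Corpus and result I/O
#'
#' @description
#' On-disk interchange: one PCM16 WAV and one TSV (`time_s`, `lio_mm`,
#' `ttu_mm`) per utterance plus a corpus manifest CSV; result tables are CSV
#' with a comment header carrying the config hash and seed, summaries are
#' JSON. 3D-sensor TSVs (`time_s`, then `x`,`y`,`z` per sensor) are also
#' accepted and converted through [euclidean_distance()].
#'
#' @name cli_io
NULL

#' Write a corpus to disk
#'
#' @param corpus a [make_corpus()] result.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly. The manifest gains `wav_path` /
#'   `tsv_path` columns (relative to `dir`).
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- corpus$manifest
  man$wav_path <- paste0(man$utterance_id, ".wav")
  man$tsv_path <- paste0(man$utterance_id, ".tsv")
  for (i in seq_len(nrow(man))) {
    utt <- corpus$utterances[[man$utterance_id[i]]]
    write_wav(utt$audio, file.path(dir, man$wav_path[i]), utt$fs_audio)
    tsv <- data.frame(time_s = (seq_along(utt$lio) - 1) / utt$fs_motor,
                      lio_mm = utt$lio, ttu_mm = utt$ttu)
    utils::write.table(format(tsv, digits = 10, trim = TRUE, scientific = FALSE),
                       file.path(dir, man$tsv_path[i]),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  path <- file.path(dir, "manifest.csv")
  meta_header(path, corpus$config, corpus$seed)
  suppressWarnings(utils::write.table(man, path, sep = ",", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

# linear-interpolation resampling (logged by the caller)
resample_wave <- function(wave, fs_from, fs_to) {
  if (fs_from == fs_to) return(wave)
  n_out <- round(length(wave) * fs_to / fs_from)
  stats::approx(seq_along(wave), wave, xout = seq(1, length(wave),
                                                  length.out = n_out))$y
}

#' Load a corpus from a manifest
#'
#' Decodes each record's WAV (resampling to `cfg$fs_audio` if the file's rate
#' differs, with a message) and TSV trajectories. Records with missing files,
#' malformed or non-monotone time columns, or audio/motor spans disagreeing
#' by more than one motor sample are rejected individually with a diagnostic;
#' the remainder load normally.
#'
#' @param manifest_path manifest CSV written by [write_corpus()].
#' @param cfg a [mi_config()] list.
#' @return a `motorinv_corpus`-shaped list with `utterances`, `manifest`
#'   (accepted records) and `rejected` (data.frame of id + reason).
#' @export
read_corpus <- function(manifest_path, cfg = mi_config()) {
  man <- utils::read.csv(manifest_path, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (nrow(man) == 0) {
    warning("empty manifest: ", manifest_path)
    return(structure(list(utterances = list(), manifest = man,
                          rejected = data.frame(), config = cfg),
                     class = "motorinv_corpus"))
  }
  dir <- dirname(manifest_path)
  utts <- list(); ok <- logical(nrow(man)); reasons <- character(0); rej_ids <- character(0)
  for (i in seq_len(nrow(man))) {
    id <- man$utterance_id[i]
    res <- tryCatch({
      wav <- read_wav(file.path(dir, man$wav_path[i]))
      if (wav$fs != cfg$fs_audio) {
        message("resampling ", id, ": ", wav$fs, " -> ", cfg$fs_audio, " Hz")
        wav$wave <- resample_wave(wav$wave, wav$fs, cfg$fs_audio)
      }
      tsv <- utils::read.delim(file.path(dir, man$tsv_path[i]))
      if (!all(c("time_s", "lio_mm", "ttu_mm") %in% names(tsv))) {
        stop("TSV lacks required columns")
      }
      if (any(!is.finite(as.matrix(tsv)))) stop("non-finite TSV values")
      if (any(diff(tsv$time_s) <= 0)) stop("non-monotone time column")
      span_motor <- nrow(tsv) / cfg$fs_motor
      span_audio <- length(wav$wave) / cfg$fs_audio
      if (abs(span_motor - span_audio) > 1 / cfg$fs_motor) {
        stop("audio/motor spans differ by more than one motor sample")
      }
      list(audio = wav$wave, lio = tsv$lio_mm, ttu = tsv$ttu_mm,
           truth_t1_s = man$truth_t1_s[i], truth_t2_s = man$truth_t2_s[i],
           fs_audio = cfg$fs_audio, fs_motor = cfg$fs_motor)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rej_ids <- c(rej_ids, id); reasons <- c(reasons, conditionMessage(res))
    } else {
      utts[[id]] <- res; ok[i] <- TRUE
    }
  }
  structure(list(utterances = utts, manifest = man[ok, , drop = FALSE],
                 rejected = data.frame(utterance_id = rej_ids, reason = reasons,
                                       stringsAsFactors = FALSE),
                 config = cfg),
            class = "motorinv_corpus")
}

meta_header <- function(path, cfg, seed) {
  writeLines(c(paste0("# config_hash: ", config_hash(cfg)),
               paste0("# seed: ", seed)), path)
}

#' Write a stamped result table
#'
#' CSV with a two-line comment header recording the configuration hash and
#' seed, so every output traces back to the exact run that produced it.
#'
#' @param df data.frame.
#' @param path output CSV path.
#' @param cfg configuration used for the run.
#' @param seed master seed used for the run.
#' @export
write_result_csv <- function(df, path, cfg, seed) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  meta_header(path, cfg, seed)
  suppressWarnings(utils::write.table(df, path, sep = ",", quote = TRUE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Read a stamped result table
#'
#' @param path CSV written by [write_result_csv()].
#' @return the data.frame, with attributes `config_hash` and `seed`.
#' @export
read_result_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "config_hash") <- sub("^# config_hash: ", "", hdr[1])
  attr(df, "seed") <- as.integer(sub("^# seed: ", "", hdr[2]))
  df
}

#' Write experiment results to a directory
#'
#' Writes `per_split.csv`, `summary.csv`, pairwise `tests.csv` (when present)
#' and a `summary.json` carrying the same content plus run metadata.
#'
#' @param result an `experiment_result`.
#' @param out_dir output directory.
#' @param cfg,seed run configuration and master seed (stamped into every
#'   file).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(result, out_dir, cfg, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_result_csv(result$per_split, file.path(out_dir, "per_split.csv"), cfg, seed)
  write_result_csv(result$summary, file.path(out_dir, "summary.csv"), cfg, seed)
  if (!is.null(result$tests) && nrow(result$tests) > 0) {
    write_result_csv(result$tests, file.path(out_dir, "tests.csv"), cfg, seed)
  }
  js <- list(config_hash = config_hash(cfg), seed = seed,
             summary = result$summary, tests = result$tests)
  jsonlite::write_json(js, file.path(out_dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out_dir)
}

#' Write a vetted segment table
#'
#' @param segments a [segment_corpus()] table.
#' @param path CSV path.
#' @param cfg,seed stamp metadata.
#' @export
write_segments <- function(segments, path, cfg, seed) {
  write_result_csv(segments, path, cfg, seed)
}
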