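#' Write a mono waveform as 16-bit PCM WAV
#'
#' @param wave numeric vector in `[-1, 1]` (values are clipped).
#' @param path output file path.
#' @param fs sampling rate in Hz.
#' @export
write_wav <- function(wave, path, fs) {
  stopifnot(is.numeric(wave), length(wave) > 0, fs > 0)
  pcm <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs) * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF parser for the files this pipeline writes: walks the chunk
#' list, requires PCM mono 16-bit, and returns samples scaled to `[-1, 1]`.
#'
#' @param path WAV file path.
#' @return list with `wave` (numeric vector) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", size = 4, endian = "little")
  wave_tag <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave_tag, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path)
  }
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      fs <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L || bits != 16L) {
        stop("only mono 16-bit PCM supported: ", path)
      }
      extra <- size - 16L
      if (extra > 0) readBin(con, "raw", n = extra)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", n = size %/% 2L, size = 2,
                     endian = "little", signed = TRUE)
      if (is.null(fs)) stop("data chunk precedes fmt chunk in ", path)
      return(list(wave = pcm / 32767, fs = fs))
    } else {
      readBin(con, "raw", n = size + (size %% 2L))
    }
  }
}
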