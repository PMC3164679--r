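#' @title Spectral primitives
#' @description Hamming-windowed short-time spectra, Mel filterbanks and
#'   cepstral coefficients used by the audio-motor map and the audio feature
#'   encoding.
#' @name dsp
NULL

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular Mel filterbank
#'
#' @param n_mel number of filters.
#' @param nfft FFT length.
#' @param fs sampling rate (Hz).
#' @param band_hz `(low, high)` band edges in Hz.
#' @return `n_mel x (nfft/2 + 1)` matrix with attribute `centers_hz`.
#' @export
mel_filterbank <- function(n_mel, nfft, fs, band_hz) {
  mel_pts <- seq(hz_to_mel(band_hz[1]), hz_to_mel(band_hz[2]), length.out = n_mel + 2)
  hz_pts <- mel_to_hz(mel_pts)
  bin_hz <- (0:(nfft / 2)) * fs / nfft
  fb <- matrix(0, n_mel, length(bin_hz))
  for (m in seq_len(n_mel)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- bin_hz >= lo & bin_hz <= ce
    dn <- bin_hz > ce & bin_hz <= hi
    fb[m, up] <- (bin_hz[up] - lo) / max(ce - lo, 1e-9)
    fb[m, dn] <- (hi - bin_hz[dn]) / max(hi - ce, 1e-9)
  }
  attr(fb, "centers_hz") <- hz_pts[2:(n_mel + 1)]
  fb
}

#' Log-Mel spectrogram over sliding Hamming windows
#'
#' Magnitude-squared spectra of `win_ms`-long Hamming-windowed slices taken
#' every `hop_ms`, projected through a triangular Mel filterbank spanning
#' `band_hz`, then log-compressed. One row per slice.
#'
#' @param wave numeric waveform.
#' @param fs sampling rate (Hz).
#' @param win_ms slice length (ms).
#' @param hop_ms slice step (ms); the overlap is `win_ms - hop_ms`.
#' @param n_mel Mel filter count.
#' @param band_hz band edges (Hz).
#' @return `n_slices x n_mel` matrix with attributes `slice_times_s` (slice
#'   centers, seconds from waveform start) and `centers_hz`.
#' @export
mel_spectrogram <- function(wave, fs, win_ms = 20, hop_ms = 10, n_mel = 24,
                            band_hz = c(100, 8000)) {
  win <- round(win_ms / 1000 * fs)
  hop <- round(hop_ms / 1000 * fs)
  if (length(wave) < win) stop("waveform shorter than one analysis window")
  nfft <- 2^ceiling(log2(win))
  fb <- mel_filterbank(n_mel, nfft, fs, band_hz)
  hamm <- 0.54 - 0.46 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  n_slices <- (length(wave) - win) %/% hop + 1
  starts <- (seq_len(n_slices) - 1) * hop
  out <- matrix(0, n_slices, n_mel)
  for (s in seq_len(n_slices)) {
    x <- wave[starts[s] + seq_len(win)] * hamm
    spec <- Mod(stats::fft(c(x, numeric(nfft - win))))[1:(nfft / 2 + 1)]^2
    out[s, ] <- log(pmax(as.numeric(fb %*% spec), 1e-10))
  }
  attr(out, "slice_times_s") <- (starts + win / 2) / fs
  attr(out, "centers_hz") <- attr(fb, "centers_hz")
  out
}

# orthonormal DCT-II matrix (n_cep x n_mel), applied to log-Mel rows
dct_matrix <- function(n_cep, n_mel) {
  M <- outer(0:(n_cep - 1), 0:(n_mel - 1),
             function(k, j) cos(pi * k * (j + 0.5) / n_mel))
  M * sqrt(2 / n_mel)
}

#' Mel-cepstral coefficients of one or more log-Mel slices
#'
#' DCT-II of each log-Mel row, truncated to `n_cep` coefficients (the first
#' one carries overall log energy).
#'
#' @param logmel `n_slices x n_mel` matrix (rows = slices).
#' @param n_cep number of cepstral coefficients to keep.
#' @return `n_slices x n_cep` matrix.
#' @export
mel_cepstra <- function(logmel, n_cep = 13) {
  logmel <- rbind(logmel)
  if (n_cep > ncol(logmel)) stop("n_cep cannot exceed the Mel filter count")
  logmel %*% t(dct_matrix(n_cep, ncol(logmel)))
}

#' Spectral centroid of a waveform
#'
#' Power-weighted mean frequency; used to characterize release bursts (low
#' for bilabial, high for dental).
#'
#' @param wave numeric waveform.
#' @param fs sampling rate (Hz).
#' @return centroid in Hz.
#' @export
spectral_centroid <- function(wave, fs) {
  n <- length(wave)
  spec <- Mod(stats::fft(wave))[1:(n %/% 2 + 1)]^2
  freq <- (0:(n %/% 2)) * fs / n
  sum(freq * spec) / sum(spec)
}
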