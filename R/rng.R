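#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All randomness in the pipeline flows from one master seed through named
#' substreams, so that independent stages (corpus synthesis, fold assignment,
#' network initialisation, noise injection, ...) draw from decoupled,
#' individually reproducible streams. The stream name and any extra integer
#' indices are folded into the seed with a polynomial string hash modulo
#' 2^31 - 1, keeping the result a valid 32-bit R integer.
#'
#' @param seed master seed (non-negative integer).
#' @param stream character stream name, e.g. `"synth"`.
#' @param ... optional indices (integers or short strings: speaker number,
#'   schema name, fold number, ...).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  fold <- function(h, x) ((h * 1315423911) %% m + x) %% m
  mix <- function(h, val) {
    if (is.character(val)) {
      for (code in utf8ToInt(val)) h <- fold(h, code)
    } else {
      h <- fold(h, as.numeric(val) %% m)
    }
    h
  }
  h <- mix(h, as.character(stream))
  for (idx in list(...)) h <- mix(h, idx)
  as.integer(h)
}

#' Evaluate an expression under a local, restored RNG state
#'
#' Sets the RNG to a derived seed for the duration of `expr` and restores the
#' caller's RNG state afterwards, so no operation reads or perturbs ambient
#' randomness.
#'
#' @param seed integer seed passed to [set.seed()].
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
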