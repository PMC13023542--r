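#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif median quantile sd cor fft coef glm binomial
#'   predict rbinom
#' @importFrom utils read.csv write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one integer seed. Independent
#' sub-streams (waveform, events, noise, ...) get their own derived seeds so
#' that components can be regenerated in isolation without perturbing each
#' other.
#'
#' @param seed Integer master seed.
#' @param stream Character name of the sub-stream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729 + 13) %% 2147483647)
}

#' Unwrap a phase sequence
#'
#' Removes artificial 2*pi jumps from a wrapped phase trajectory by mapping
#' successive differences into `(-pi, pi]` and re-integrating.
#'
#' @param p Numeric vector of phases in radians.
#' @return Numeric vector of the same length with continuous phase.
#' @export
unwrap_phase <- function(p) {
  stopifnot(is.numeric(p))
  if (length(p) < 2L) return(p)
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1L], p[1L] + cumsum(dp))
}

log_msg <- function(...) {
  if (isTRUE(getOption("apneaseg.verbose", FALSE))) {
    message(sprintf(...))
  }
  invisible(NULL)
}

# seconds -> sample-index conversion with a float-round-off guard so that
# an exact sample boundary is never pushed to the neighbouring sample
sec_to_start <- function(x, fs) as.integer(floor(x * fs + 1e-6))
sec_to_end <- function(x, fs) as.integer(ceiling(x * fs - 1e-6))

# run-length runs of TRUE as half-open [start, end) 0-based sample intervals
runs_true <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}
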