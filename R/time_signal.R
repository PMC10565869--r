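#' Uniformly sampled waveform
#'
#' `time_signal()` is the universal waveform currency of the package: a real
#' amplitude sequence (dimensionless, read as volts when levels are computed)
#' together with its sampling rate.
#'
#' @param samples Numeric vector of finite amplitudes, length >= 1.
#' @param rate_hz Sampling rate in samples per second, > 0.
#' @return An object of class `time_signal` with fields `samples` and
#'   `rate_hz`.
#' @examples
#' x <- time_signal(sin(2 * pi * 100 * seq(0, 1, by = 1 / 8000)), 8000)
#' duration_s(x)
#' level_db(x)
#' @export
time_signal <- function(samples, rate_hz) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("`samples` must have length >= 1", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("all samples must be finite", call. = FALSE)
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    stop("`rate_hz` must be a single positive number", call. = FALSE)
  }
  structure(list(samples = samples, rate_hz = as.numeric(rate_hz)),
            class = "time_signal")
}

#' @export
print.time_signal <- function(x, ...) {
  cat(sprintf("<time_signal: %d samples @ %g Hz (%.4g s), level %.2f dB re 1 V_RMS>\n",
              length(x$samples), x$rate_hz, duration_s(x), level_db(x)))
  invisible(x)
}

#' @export
length.time_signal <- function(x) length(x$samples)

is_time_signal <- function(x) inherits(x, "time_signal")

assert_time_signal <- function(x, arg = deparse(substitute(x))) {
  if (!is_time_signal(x)) {
    stop(sprintf("`%s` must be a time_signal", arg), call. = FALSE)
  }
  invisible(x)
}

assert_same_rate <- function(x, y) {
  if (!isTRUE(all.equal(x$rate_hz, y$rate_hz))) {
    stop(sprintf("sampling rates differ (%g Hz vs %g Hz)", x$rate_hz, y$rate_hz),
         call. = FALSE)
  }
  invisible(NULL)
}

#' Duration of a waveform in seconds
#' @param x A `time_signal`.
#' @return Duration `length(samples) / rate_hz` in seconds.
#' @export
duration_s <- function(x) {
  assert_time_signal(x)
  length(x$samples) / x$rate_hz
}

#' Root-mean-square amplitude
#' @param x A `time_signal` or numeric vector.
#' @return RMS amplitude (volts under the level convention).
#' @export
rms <- function(x) {
  v <- if (is_time_signal(x)) x$samples else as.numeric(x)
  sqrt(mean(v^2))
}

#' Signal level in dB re 1 V RMS
#'
#' The package-wide level convention: `level_db(x) = 20 log10(RMS(x) / 1)`.
#' A unit-amplitude sine therefore reads -3.01 dB re 1 V_RMS.
#'
#' @param x A `time_signal` or numeric vector.
#' @return Level in dB re 1 V RMS (`-Inf` for all-zero input).
#' @export
level_db <- function(x) {
  r <- rms(x)
  if (r == 0) return(-Inf)
  20 * log10(r)
}

#' Scale a waveform to an exact RMS level
#' @param x A `time_signal`.
#' @param level_db Target level in dB re 1 V RMS.
#' @return A `time_signal` whose RMS equals `10^(level_db/20)`.
#' @export
set_level <- function(x, level_db) {
  assert_time_signal(x)
  r <- rms(x)
  if (r == 0) stop("cannot set the level of an all-zero signal", call. = FALSE)
  time_signal(x$samples * (10^(level_db / 20) / r), x$rate_hz)
}

# Full linear convolution via FFT; exact up to double-precision roundoff.
conv_full <- function(x, y) {
  nx <- length(x); ny <- length(y)
  n <- nx + ny - 1L
  nfft <- stats::nextn(n, 2L)
  out <- Re(stats::fft(stats::fft(c(x, numeric(nfft - nx))) *
                         stats::fft(c(y, numeric(nfft - ny))),
                       inverse = TRUE)) / nfft
  out[seq_len(n)]
}

#' Linear convolution of two waveforms
#' @param x,y `time_signal`s at the same rate.
#' @return The full convolution, length `length(x) + length(y) - 1`.
#' @export
convolve_signals <- function(x, y) {
  assert_time_signal(x); assert_time_signal(y)
  assert_same_rate(x, y)
  time_signal(conv_full(x$samples, y$samples), x$rate_hz)
}

# Evaluate expr with a private RNG stream; the caller's RNG state is untouched.
# All stochastic generators in the package are pure functions of
# (parameters, seed) through this helper.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Derive a child seed from a master seed and a stage counter, kept within
# 32-bit integer range.
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 7919 + 104729 * as.numeric(stage)) %%
               .Machine$integer.max)
}
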