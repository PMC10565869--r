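#' Time-stretched pulse (swept sine) and its exact inverse
#'
#' Builds an optimized TSP pair in the frequency domain:
#' `H(k) = exp(-i 4 pi m k^2 / N^2)` for `0 <= k <= N/2`, completed by Hermitian
#' symmetry, with `m = stretch`. The magnitude spectrum is exactly flat, so the
#' spectral conjugate is an exact circular inverse: circular convolution of
#' sweep and inverse is a unit impulse at lag zero. The sweep's group delay
#' grows from 0 at DC to `2 m` samples at Nyquist, so it starts near t = 0 and
#' occupies roughly the first `2 m` samples of the buffer.
#'
#' @param n_samples Even FFT length N (the measurement-protocol value used
#'   elsewhere in the package is 32728, i.e. 2.05 s at 16 kHz).
#' @param stretch Integer stretch parameter m >= 1. Default `n_samples %/% 8`,
#'   which keeps the effective sweep within a quarter of the buffer.
#' @param rate_hz Sampling rate in Hz.
#' @return A `tsp_pair`: list with `sweep` and `inverse` (`time_signal`s of
#'   identical length and rate, sweep peak-normalized to 1), `n_samples`,
#'   `stretch`, and `delay` (the sample offset, 0-based, at which
#'   [deconvolve()] places a response relative to the sweep onset: 0).
#' @examples
#' tsp <- generate_tsp(4096, rate_hz = 16000)
#' duration_s(tsp$sweep)
#' @export
generate_tsp <- function(n_samples, stretch = n_samples %/% 8L, rate_hz) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples <= 0 ||
      n_samples != round(n_samples)) {
    stop("`n_samples` must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n_samples)
  if (n %% 2L != 0L) stop("`n_samples` must be even", call. = FALSE)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop("`rate_hz` must be positive", call. = FALSE)
  }
  m <- as.integer(stretch)
  if (m < 1L) stop("`stretch` must be >= 1", call. = FALSE)
  if (2L * m > n) {
    warning("stretch > n_samples/2: the sweep no longer fits its buffer",
            call. = FALSE)
  }
  k <- 0:(n %/% 2L)
  half <- exp(-1i * 4 * pi * m * (as.numeric(k)^2) / as.numeric(n)^2)
  spec <- complex(length.out = n)
  spec[k + 1L] <- half
  if (n %/% 2L > 1L) {
    kk <- 1:(n %/% 2L - 1L)
    spec[n - kk + 1L] <- Conj(half[kk + 1L])
  }
  sweep <- Re(stats::fft(spec, inverse = TRUE)) / n
  peak <- max(abs(sweep))
  sweep <- sweep / peak
  inverse <- Re(stats::fft(Conj(spec), inverse = TRUE)) / n * peak
  structure(list(sweep = time_signal(sweep, rate_hz),
                 inverse = time_signal(inverse, rate_hz),
                 n_samples = n, stretch = m, delay = 0L),
            class = "tsp_pair")
}

#' @export
print.tsp_pair <- function(x, ...) {
  cat(sprintf("<tsp_pair: N = %d (%.4g s @ %g Hz), stretch = %d>\n",
              x$n_samples, duration_s(x$sweep), x$sweep$rate_hz, x$stretch))
  invisible(x)
}

#' Deconvolve a recording with the inverse TSP
#'
#' Exact deconvolution of a sweep recording: when the recording is the sweep
#' (possibly delayed by an onset) passed through an impulse response `h`, the
#' output contains `h` exactly at the sweep's onset offset. Internally the
#' sweep spectrum is reconstructed from the inverse (the two are conjugate,
#' constant-magnitude spectra by construction) and the recording is divided by
#' it on an FFT grid long enough that linear convolution is invertible; the
#' zero-padded sweep spectrum has no small bins (its magnitude spread is about
#' a factor 2.5), so the division is well conditioned and recovers embedded
#' responses to machine precision in the noiseless case.
#'
#' @param recorded Recorded `time_signal` (length >= inverse length).
#' @param inverse The inverse sweep (`time_signal`, from [generate_tsp()]).
#' @return The full deconvolved sequence as a `time_signal`, the same length
#'   as the recording; an impulse response driven by a sweep starting at
#'   sample `o` (0-based) appears at sample `o` of the output.
#' @export
deconvolve <- function(recorded, inverse) {
  assert_time_signal(recorded); assert_time_signal(inverse)
  assert_same_rate(recorded, inverse)
  n <- length(inverse$samples)
  L <- length(recorded$samples)
  if (L < n) {
    stop("recording is shorter than the inverse sweep", call. = FALSE)
  }
  # sweep spectrum from the inverse: fft(inverse) = a * conj(H) with |H| = 1
  si <- stats::fft(inverse$samples)
  a2 <- Mod(si[2])^2  # a^2; bin 2 avoids any DC scaling ambiguity
  sweep <- Re(stats::fft(Conj(si), inverse = TRUE)) / n / a2
  m <- stats::nextn(L + n, 2)
  S <- stats::fft(c(sweep, numeric(m - n)))
  Y <- stats::fft(c(recorded$samples, numeric(m - L)))
  x <- Re(stats::fft(Y / S, inverse = TRUE)) / m
  time_signal(x[seq_len(L)], recorded$rate_hz)
}

#' Extract a fixed-length impulse response from a deconvolved recording
#'
#' @param full The deconvolved `time_signal`.
#' @param start_index 1-based index of the first sample to keep.
#' @param length Number of samples to keep; the default 512 is 32 ms at
#'   16 kHz.
#' @return A `time_signal` holding the contiguous slice.
#' @export
extract_ir <- function(full, start_index, length = 512L) {
  assert_time_signal(full)
  start_index <- as.integer(start_index)
  length <- as.integer(length)
  if (length < 1L) stop("`length` must be >= 1", call. = FALSE)
  if (start_index < 1L || start_index + length - 1L > base::length(full$samples)) {
    stop("requested slice is out of range", call. = FALSE)
  }
  time_signal(full$samples[start_index:(start_index + length - 1L)],
              full$rate_hz)
}

#' Locate the onset of an impulse response
#'
#' Peak-referenced onset heuristic: the first sample whose magnitude exceeds
#' `frac` of the global peak, minus a guard interval.
#'
#' @param x A `time_signal`.
#' @param frac Fraction of the peak magnitude treated as signal onset.
#' @param guard_samples Samples to step back from the detected onset.
#' @return 1-based index suitable as `start_index` for [extract_ir()].
#' @export
find_ir_onset <- function(x, frac = 0.05, guard_samples = 0L) {
  assert_time_signal(x)
  a <- abs(x$samples)
  peak <- max(a)
  if (peak == 0) stop("all-zero signal has no onset", call. = FALSE)
  idx <- which(a >= frac * peak)[1L]
  max(1L, idx - as.integer(guard_samples))
}
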