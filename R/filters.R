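#' One-third-octave band edges
#'
#' Base-2 third-octave edges: `f_lo = center * 2^(-1/6)`,
#' `f_hi = center * 2^(1/6)`, so `f_hi / f_lo = 2^(1/3)` exactly. The 250 and
#' 1000 Hz centers give the 224-1122 Hz working band used throughout the
#' cancellation pipeline.
#'
#' @param center_hz Band center frequency, > 0.
#' @return Named numeric vector `c(f_lo_hz =, f_hi_hz =)`.
#' @examples
#' third_octave_band(1000)
#' @export
third_octave_band <- function(center_hz) {
  if (!is.numeric(center_hz) || length(center_hz) != 1L || center_hz <= 0) {
    stop("`center_hz` must be a single positive number", call. = FALSE)
  }
  c(f_lo_hz = center_hz * 2^(-1 / 6), f_hi_hz = center_hz * 2^(1 / 6))
}

# The seven probe frequencies of the subjective evaluation: third-octave
# centers (base-2 series rounded as in the source protocol).
probe_frequencies <- function() c(250, 315, 397, 500, 630, 794, 1000)

check_band <- function(f_lo, f_hi, rate_hz) {
  if (!(f_lo > 0 && f_hi > f_lo && f_hi < rate_hz / 2)) {
    stop(sprintf("invalid band [%g, %g] Hz at rate %g Hz (need 0 < lo < hi < Nyquist)",
                 f_lo, f_hi, rate_hz), call. = FALSE)
  }
  invisible(NULL)
}

# Zero-phase Butterworth bandpass (order `order` per side, applied
# forward-backward).
butter_bandpass <- function(x, rate_hz, f_lo, f_hi, order = 4L) {
  ba <- signal::butter(order, c(f_lo, f_hi) * 2 / rate_hz, type = "pass")
  as.numeric(signal::filtfilt(ba, x))
}

#' Band-limited Gaussian noise
#'
#' White Gaussian noise shaped by an 8th-order Butterworth bandpass (4th order
#' per side, applied forward-backward so the response is zero-phase and the
#' stopband rejection one octave beyond each edge exceeds 40 dB). The default
#' band, 224-1122 Hz, spans the third-octave edges of the 250 and 1000 Hz
#' cancellation targets. Output is normalized to unit RMS.
#'
#' @param rate_hz Sampling rate in Hz.
#' @param duration_s Duration in seconds.
#' @param f_lo_hz,f_hi_hz Passband edges in Hz.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return A `time_signal` of `round(rate_hz * duration_s)` samples.
#' @export
bandpass_noise <- function(rate_hz, duration_s, f_lo_hz = 224, f_hi_hz = 1122,
                           seed) {
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  check_band(f_lo_hz, f_hi_hz, rate_hz)
  n <- round(rate_hz * duration_s)
  x <- with_seed(seed, stats::rnorm(n))
  y <- butter_bandpass(x, rate_hz, f_lo_hz, f_hi_hz, order = 4L)
  time_signal(y / sqrt(mean(y^2)), rate_hz)
}

#' Zero-phase high-pass filter
#'
#' 4th-order Butterworth high-pass applied forward-backward. Used to strip DC
#' and sub-audio drift from simulated sensor recordings before deconvolution.
#'
#' @param x A `time_signal`.
#' @param cutoff_hz Cutoff frequency (default 100 Hz).
#' @return Filtered `time_signal` of the same length.
#' @export
highpass <- function(x, cutoff_hz = 100) {
  assert_time_signal(x)
  if (!(cutoff_hz > 0 && cutoff_hz < x$rate_hz / 2)) {
    stop("`cutoff_hz` must lie in (0, Nyquist)", call. = FALSE)
  }
  ba <- signal::butter(4L, cutoff_hz * 2 / x$rate_hz, type = "high")
  time_signal(as.numeric(signal::filtfilt(ba, x$samples)), x$rate_hz)
}

#' Band-limited level of a waveform
#'
#' Level in dB re 1 V RMS after zero-phase Butterworth bandpass filtering,
#' optionally excluding an edge window at both ends before the RMS is taken
#' (steady-state convention used by the verification stage).
#'
#' @param x A `time_signal`.
#' @param f_lo_hz,f_hi_hz Analysis band in Hz.
#' @param edge_s Seconds excluded at each end (default 0).
#' @return Level in dB re 1 V RMS.
#' @export
band_level_db <- function(x, f_lo_hz, f_hi_hz, edge_s = 0) {
  assert_time_signal(x)
  check_band(f_lo_hz, f_hi_hz, x$rate_hz)
  y <- butter_bandpass(x$samples, x$rate_hz, f_lo_hz, f_hi_hz, order = 4L)
  n <- length(y)
  drop <- round(edge_s * x$rate_hz)
  if (2 * drop >= n) stop("edge windows longer than the signal", call. = FALSE)
  seg <- y[(drop + 1L):(n - drop)]
  if (all(seg == 0)) return(-Inf)
  20 * log10(sqrt(mean(seg^2)))
}

# Magnitude spectrum (linear) of a tap vector on an n_fft grid; returns
# frequencies and magnitudes for bins 0 .. n_fft/2.
magnitude_spectrum <- function(taps, rate_hz, n_fft = 4096L) {
  n_fft <- max(as.integer(n_fft), length(taps))
  spec <- stats::fft(c(taps, numeric(n_fft - length(taps))))
  half <- 0:(n_fft %/% 2L)
  list(freq_hz = half * rate_hz / n_fft, mag = abs(spec[half + 1L]))
}
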