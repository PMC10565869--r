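#' Frequency-dependent regularization profile
#'
#' Parametric description of the regularization function eps(w) used by the
#' Kirkeby inverse: a floor `eps_min` strictly inside `[f_low_hz, f_high_hz]`,
#' `eps_max` far outside, joined by raised-cosine ramps in log-frequency over
#' `transition_octaves`. Values are relative to `max |T(w)|^2` of the response
#' being inverted (scaled inside [kirkeby_inverse()]), so profiles transfer
#' between responses of different gain.
#'
#' @param eps_min In-band regularization floor, >= 0. Default 1e-4.
#' @param eps_max Out-of-band regularization, > eps_min. Default 1.
#' @param f_low_hz,f_high_hz Equalized band edges in Hz (defaults 200 and
#'   4000, the transducer-equalization working range).
#' @param transition_octaves Width of each raised-cosine transition in
#'   octaves, > 0. Default 0.5.
#' @return A `reg_profile` object.
#' @export
reg_profile <- function(eps_min = 1e-4, eps_max = 1, f_low_hz = 200,
                        f_high_hz = 4000, transition_octaves = 0.5) {
  if (!(eps_min >= 0 && eps_max > eps_min)) {
    stop("need 0 <= eps_min < eps_max", call. = FALSE)
  }
  if (!(f_low_hz > 0 && f_high_hz > f_low_hz)) {
    stop("need 0 < f_low_hz < f_high_hz", call. = FALSE)
  }
  if (transition_octaves <= 0) stop("`transition_octaves` must be > 0", call. = FALSE)
  structure(list(eps_min = eps_min, eps_max = eps_max, f_low_hz = f_low_hz,
                 f_high_hz = f_high_hz, transition_octaves = transition_octaves),
            class = "reg_profile")
}

#' @export
print.reg_profile <- function(x, ...) {
  cat(sprintf("<reg_profile: eps %g..%g, band %g-%g Hz, transition %g oct>\n",
              x$eps_min, x$eps_max, x$f_low_hz, x$f_high_hz,
              x$transition_octaves))
  invisible(x)
}

#' Evaluate a regularization profile on an FFT bin grid
#'
#' @param profile A [reg_profile()].
#' @param n_bins FFT length (>= 2); the returned vector follows the standard
#'   Hermitian-symmetric DFT bin layout (bin k corresponds to frequency
#'   `min(k, n_bins - k) * rate_hz / n_bins`).
#' @param rate_hz Sampling rate in Hz.
#' @return Numeric vector of length `n_bins` with eps at each bin.
#' @export
regularization_vector <- function(profile, n_bins, rate_hz) {
  stopifnot(inherits(profile, "reg_profile"))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("`n_bins` must be >= 2", call. = FALSE)
  if (profile$f_high_hz >= rate_hz / 2) {
    stop("profile band extends beyond Nyquist", call. = FALSE)
  }
  k <- 0:(n_bins - 1L)
  f <- pmin(k, n_bins - k) * rate_hz / n_bins
  eps_at <- function(f) {
    t <- profile$transition_octaves
    lo <- profile$f_low_hz; hi <- profile$f_high_hz
    out <- numeric(length(f))
    out[f <= 0] <- profile$eps_max
    pos <- f > 0
    lf <- log2(f[pos])
    # 0 = fully out of band, 1 = fully in band
    w_lo <- pmin(pmax((lf - (log2(lo) - t)) / t, 0), 1)
    w_hi <- pmin(pmax(((log2(hi) + t) - lf) / t, 0), 1)
    w <- pmin(w_lo, w_hi)
    w <- sin(pi / 2 * w)^2  # raised-cosine in log-frequency
    out[pos] <- profile$eps_max + (profile$eps_min - profile$eps_max) * w
    out
  }
  eps_at(f)
}

#' Kirkeby regularized inverse filter
#'
#' Frequency-domain regularized inversion of an impulse response `T(w)`:
#' `C(w) = conj(T(w)) / (conj(T(w)) T(w) + eps(w))`, with the
#' frequency-dependent `eps(w)` taken from `profile` and scaled by
#' `max |T(w)|^2`. The time-domain taps are circularly shifted by
#' `modeling_delay` samples so the mixed-phase inverse becomes causal. At every
#' bin `|C| <= 1 / (2 sqrt(eps))`, which is what keeps the filter from boosting
#' frequencies where the transducer is weak.
#'
#' @param ir The impulse response to invert (`time_signal`).
#' @param profile A [reg_profile()]; eps values are relative to
#'   `max |T(w)|^2`.
#' @param n_fft FFT length, >= 2 x the response length (default 4096).
#' @param modeling_delay Causality shift in samples (default `n_fft / 2`).
#' @return An `eq_filter`: list with `taps` (numeric, length `n_fft`),
#'   `rate_hz`, `modeling_delay`.
#' @export
kirkeby_inverse <- function(ir, profile, n_fft = 4096L,
                            modeling_delay = n_fft %/% 2L) {
  assert_time_signal(ir)
  stopifnot(inherits(profile, "reg_profile"))
  n_fft <- as.integer(n_fft)
  if (n_fft < 2L * length(ir$samples)) {
    stop("`n_fft` must be at least twice the response length", call. = FALSE)
  }
  modeling_delay <- as.integer(modeling_delay)
  if (modeling_delay < 0L || modeling_delay >= n_fft) {
    stop("`modeling_delay` must lie in [0, n_fft)", call. = FALSE)
  }
  T_ <- stats::fft(c(ir$samples, numeric(n_fft - length(ir$samples))))
  scale <- max(Mod(T_)^2)
  if (scale == 0 && profile$eps_min == 0) {
    stop("singular inversion: all-zero response with eps_min = 0", call. = FALSE)
  }
  eps <- regularization_vector(profile, n_fft, ir$rate_hz) * scale
  denom <- Mod(T_)^2 + eps
  if (any(denom == 0)) {
    stop("singular inversion: zero response magnitude with zero regularization",
         call. = FALSE)
  }
  C_ <- Conj(T_) / denom
  # circular shift by modeling_delay: multiply by a linear phase
  k <- 0:(n_fft - 1L)
  C_ <- C_ * exp(-2i * pi * k * modeling_delay / n_fft)
  taps <- Re(stats::fft(C_, inverse = TRUE)) / n_fft
  structure(list(taps = taps, rate_hz = ir$rate_hz,
                 modeling_delay = modeling_delay),
            class = "eq_filter")
}

#' @export
print.eq_filter <- function(x, ...) {
  cat(sprintf("<eq_filter: %d taps @ %g Hz, modeling delay %d samples>\n",
              length(x$taps), x$rate_hz, x$modeling_delay))
  invisible(x)
}

#' Apply an equalization filter to an impulse response
#'
#' Full linear convolution of the response with the inverse-filter taps; the
#' result carries the filter's modeling delay.
#'
#' @param ir A `time_signal`.
#' @param eq An `eq_filter` from [kirkeby_inverse()].
#' @return A `time_signal` of length `length(ir) + length(taps) - 1`.
#' @export
apply_equalization <- function(ir, eq) {
  assert_time_signal(ir)
  stopifnot(inherits(eq, "eq_filter"))
  if (!isTRUE(all.equal(ir$rate_hz, eq$rate_hz))) {
    stop("sampling rates differ between response and filter", call. = FALSE)
  }
  time_signal(conv_full(ir$samples, eq$taps), ir$rate_hz)
}

#' In-band spectral flatness of a response
#'
#' Max minus min magnitude (dB) across the analysis band after one-third-octave
#' power smoothing. 0 dB for a pure delay/impulse; small values mean the
#' response is flat over the band (the goal of transducer equalization).
#'
#' @param ir A `time_signal`.
#' @param f_lo_hz,f_hi_hz Analysis band in Hz.
#' @param n_fft FFT grid (default 8192).
#' @return Ripple in dB.
#' @export
flatness_metric <- function(ir, f_lo_hz, f_hi_hz, n_fft = 8192L) {
  assert_time_signal(ir)
  check_band(f_lo_hz, f_hi_hz, ir$rate_hz)
  sp <- magnitude_spectrum(ir$samples, ir$rate_hz, n_fft)
  pow <- sp$mag^2
  in_band <- which(sp$freq_hz >= f_lo_hz & sp$freq_hz <= f_hi_hz)
  if (length(in_band) == 0L) stop("empty analysis band", call. = FALSE)
  smoothed <- vapply(in_band, function(i) {
    f <- sp$freq_hz[i]
    win <- sp$freq_hz >= f * 2^(-1 / 6) & sp$freq_hz <= f * 2^(1 / 6)
    mean(pow[win])
  }, numeric(1))
  10 * (log10(max(smoothed)) - log10(min(smoothed)))
}
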