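#' FxLMS estimation settings
#'
#' Configuration of the filtered-x LMS loop that estimates the
#' crosstalk-compensation (CTC) filter. The defaults mirror the measurement
#' protocol: a 512-tap filter adapted for 60 s of 224-1122 Hz band-limited
#' noise (the third-octave edges of the 250-1000 Hz cancellation range).
#' The printed update rule `w(n+1) = w(n) - mu e(n) s_Rf(n)` is scale
#' sensitive, so by default the step is power-normalized,
#' `mu / (||s_Rf||^2 + delta)`; set `normalized = FALSE` for the raw rule.
#'
#' @param p CTC filter length in taps (default 512).
#' @param mu Learning rate (default 0.02; the filtered-x loop on modal
#'   secondary paths becomes unstable near 0.05-0.08, so the default keeps a
#'   factor ~3 margin).
#' @param duration_s Length of the adaptation signal in seconds (default 60).
#' @param band Input-noise passband in Hz (default `c(224, 1122)`).
#' @param normalized Use the power-normalized step (default `TRUE`).
#' @param delta Normalization regularizer (default 1e-8).
#' @param convergence_tol Per-block relative coefficient-change tolerance used
#'   by [check_convergence()] (default 0.01, i.e. the filter is called
#'   converged once it changes by less than 1 percent per block for five
#'   consecutive blocks; the steady-state change floor of the normalized
#'   update sits near 0.2-0.7 percent).
#' @param seed Seed for the adaptation noise (default 1).
#' @return An `fxlms_config` object.
#' @export
fxlms_config <- function(p = 512L, mu = 0.02, duration_s = 60,
                         band = c(224, 1122), normalized = TRUE,
                         delta = 1e-8, convergence_tol = 1e-2, seed = 1L) {
  if (mu <= 0) stop("`mu` must be > 0", call. = FALSE)
  if (duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
  structure(list(p = as.integer(p), mu = mu, duration_s = duration_s,
                 band = band, normalized = isTRUE(normalized), delta = delta,
                 convergence_tol = convergence_tol, seed = as.integer(seed)),
            class = "fxlms_config")
}

#' Filtered-x (filtered-reference) signal
#'
#' Causal convolution of the reference input with the secondary-path estimate
#' `c_LL`, truncated to the input length. In simulation `c_LL` equals the true
#' secondary path `h_LL`.
#'
#' @param signal Reference `time_signal`.
#' @param c_ll Secondary-path estimate (`time_signal`).
#' @return A `time_signal` the same length as `signal`.
#' @export
filtered_x <- function(signal, c_ll) {
  assert_time_signal(signal); assert_time_signal(c_ll)
  assert_same_rate(signal, c_ll)
  y <- conv_full(signal$samples, c_ll$samples)[seq_along(signal$samples)]
  time_signal(y, signal$rate_hz)
}

#' Estimate the crosstalk-compensation filter by FxLMS
#'
#' Runs the sample-wise filtered-x LMS loop: band-limited noise `s_R` drives
#' the (virtual) right transducer; the error at the sensor is
#' `e(n) = (s_R * h_RL)(n) + (anti_s_R * h_LL)(n)` with
#' `anti_s_R(n) = w(n)^T s_R_vec(n)`, and coefficients follow
#' `w(n+1) = w(n) - mu e(n) s_Rf(n)` (power-normalized step by default).
#' Coefficients start at zero.
#'
#' @param paths A `path_pair` (h_RL primary, h_LL secondary).
#' @param config An [fxlms_config()].
#' @param c_ll Optional secondary-path estimate; defaults to the true
#'   `paths$h_secondary` (the simulation convention). Pass a perturbed
#'   response to study model mismatch.
#' @return List with `filter` (a `ctc_filter`: fields `taps`, `rate_hz`) and
#'   `trace` (an `fxlms_trace`: tibble-backed error history, per-block
#'   relative coefficient change, `converged_at_s`, `block_s`).
#' @seealso [check_convergence()], [ctc_wiener()], [measure_reduction()]
#' @export
estimate_ctc_filter <- function(paths, config = fxlms_config(), c_ll = NULL) {
  stopifnot(inherits(paths, "path_pair"), inherits(config, "fxlms_config"))
  rate <- paths$rate_hz
  check_band(config$band[1], config$band[2], rate)
  if (is.null(c_ll)) c_ll <- paths$h_secondary
  assert_time_signal(c_ll)
  sR <- bandpass_noise(rate, config$duration_s, config$band[1], config$band[2],
                       seed = config$seed)
  n <- length(sR$samples)
  d <- conv_full(sR$samples, paths$h_primary$samples)[seq_len(n)]
  xf <- conv_full(sR$samples, c_ll$samples)[seq_len(n)]
  res <- fxlms_core(sR$samples, d, xf, paths$h_secondary$samples,
                    config$p, config$mu, config$normalized, config$delta)
  if (isTRUE(res$diverged)) {
    stop(sprintf("FxLMS diverged (error energy grew > 1e6 x initial); reduce mu (currently %g)",
                 config$mu), call. = FALSE)
  }
  trace <- structure(list(error_history = as.numeric(res$error),
                          coefficient_change = as.numeric(res$coef_change),
                          rate_hz = rate, block_s = config$p / rate,
                          converged_at_s = NA_real_),
                     class = "fxlms_trace")
  trace$converged_at_s <- check_convergence(trace, config$convergence_tol)
  filt <- structure(list(taps = as.numeric(res$w), rate_hz = rate),
                    class = "ctc_filter")
  list(filter = filt, trace = trace)
}

#' @export
print.ctc_filter <- function(x, ...) {
  cat(sprintf("<ctc_filter: %d taps @ %g Hz, peak %.4g>\n",
              length(x$taps), x$rate_hz, max(abs(x$taps))))
  invisible(x)
}

#' @export
print.fxlms_trace <- function(x, ...) {
  conv <- if (is.na(x$converged_at_s)) "not converged" else
    sprintf("converged at %.2f s", x$converged_at_s)
  cat(sprintf("<fxlms_trace: %d samples (%.3g s), %d blocks, %s>\n",
              length(x$error_history), length(x$error_history) / x$rate_hz,
              length(x$coefficient_change), conv))
  invisible(x)
}

#' Earliest convergence time of an FxLMS run
#'
#' Returns the time (in seconds, at the end of the first qualifying block) at
#' which the per-block relative coefficient change stays below `tol` for 5
#' consecutive blocks, or `NA` if that never happens.
#'
#' @param trace An `fxlms_trace`.
#' @param tol Relative L2 coefficient-change tolerance.
#' @param consecutive Number of consecutive qualifying blocks (default 5).
#' @return Time in seconds, or `NA_real_`.
#' @export
check_convergence <- function(trace, tol, consecutive = 5L) {
  stopifnot(inherits(trace, "fxlms_trace"))
  ok <- trace$coefficient_change < tol
  if (length(ok) == 0L) return(NA_real_)
  run <- 0L
  for (i in seq_along(ok)) {
    run <- if (ok[i]) run + 1L else 0L
    if (run >= consecutive) {
      return((i - consecutive + 1L) * trace$block_s)
    }
  }
  NA_real_
}

#' Closed-form (Wiener) CTC solutions
#'
#' Two non-adaptive references for the CTC filter the FxLMS loop estimates.
#'
#' `method = "ls"` (default) solves the causal FIR Wiener problem exactly:
#' minimize the expected squared sensor error over the band-limited input
#' spectrum, via the Toeplitz normal equations. This is the true optimum a
#' causal `p`-tap filter can reach and upper-bounds the adaptive filter's
#' cancellation.
#'
#' `method = "division"` forms the unconstrained frequency-domain solution
#' `W(w) = -H_RL(w) conj(H_LL(w)) / (|H_LL(w)|^2 + lambda max|H_LL|^2)` and
#' truncates its inverse FFT to `p` causal taps; simple and adequate for
#' frequency-response comparisons, but its truncation discards whatever
#' acausal/wrapped energy the unconstrained solution has (fraction attached
#' as attribute `"acausal_energy"`).
#'
#' @param paths A `path_pair`.
#' @param p Filter length (default 512).
#' @param lambda Relative regularization (default 1e-4).
#' @param n_fft FFT grid (default 4096).
#' @param method `"ls"` or `"division"`.
#' @param band Input band for the `"ls"` spectrum weighting (default
#'   `c(224, 1122)`, the adaptation-noise band).
#' @return A `ctc_filter`.
#' @export
ctc_wiener <- function(paths, p = 512L, lambda = 1e-4, n_fft = 4096L,
                       method = c("ls", "division"), band = c(224, 1122)) {
  stopifnot(inherits(paths, "path_pair"))
  method <- match.arg(method)
  n_fft <- as.integer(n_fft)
  p <- as.integer(p)
  H_rl <- stats::fft(c(paths$h_primary$samples,
                       numeric(n_fft - length(paths$h_primary$samples))))
  H_ll <- stats::fft(c(paths$h_secondary$samples,
                       numeric(n_fft - length(paths$h_secondary$samples))))
  if (method == "division") {
    W <- -H_rl * Conj(H_ll) / (Mod(H_ll)^2 + lambda * max(Mod(H_ll)^2))
    w_full <- Re(stats::fft(W, inverse = TRUE)) / n_fft
    taps <- w_full[seq_len(p)]
    acausal <- sum(w_full[(n_fft - n_fft %/% 4L):n_fft]^2) / sum(w_full^2)
    return(structure(list(taps = taps, rate_hz = paths$rate_hz),
                     class = "ctc_filter", acausal_energy = acausal))
  }
  # input power spectrum: the zero-phase 8th-order Butterworth band shaping
  # used by bandpass_noise(), plus a small white floor for conditioning
  ba <- signal::butter(4L, band * 2 / paths$rate_hz, type = "pass")
  Hbp <- signal::freqz(ba$b, ba$a, n = n_fft, region = "whole",
                       Fs = paths$rate_hz)$h
  Phi <- Mod(Hbp)^4 + lambda * max(Mod(Hbp)^4)
  r_xx <- Re(stats::fft(Phi * Mod(H_ll)^2, inverse = TRUE)) / n_fft
  r_dx <- Re(stats::fft(Phi * H_rl * Conj(H_ll), inverse = TRUE)) / n_fft
  R <- stats::toeplitz(r_xx[seq_len(p)])
  taps <- as.numeric(solve(R, -r_dx[seq_len(p)]))
  structure(list(taps = taps, rate_hz = paths$rate_hz), class = "ctc_filter")
}

#' Frequency response of a tap filter
#'
#' @param taps Numeric tap vector (or a `ctc_filter` / `eq_filter`).
#' @param rate_hz Sampling rate; taken from the object if present.
#' @param n_fft FFT grid (default 4096).
#' @return Tibble with `freq_hz`, complex `response`, `mag_db`, `phase_rad`.
#' @export
filter_response <- function(taps, rate_hz = NULL, n_fft = 4096L) {
  if (is.list(taps) && !is.null(taps$taps)) {
    rate_hz <- taps$rate_hz
    taps <- taps$taps
  }
  if (is.null(rate_hz)) stop("`rate_hz` is required for bare tap vectors", call. = FALSE)
  n_fft <- max(as.integer(n_fft), length(taps))
  spec <- stats::fft(c(taps, numeric(n_fft - length(taps))))
  half <- 0:(n_fft %/% 2L)
  resp <- spec[half + 1L]
  tibble::tibble(freq_hz = half * rate_hz / n_fft,
                 response = resp,
                 mag_db = 20 * log10(pmax(Mod(resp), .Machine$double.xmin)),
                 phase_rad = Arg(resp))
}
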