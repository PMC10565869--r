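#' Stereo waveform
#'
#' @param left,right `time_signal`s of equal length and rate.
#' @return A `stereo_signal`.
#' @export
stereo_signal <- function(left, right) {
  assert_time_signal(left); assert_time_signal(right)
  assert_same_rate(left, right)
  if (length(left$samples) != length(right$samples)) {
    stop("channels must have equal length", call. = FALSE)
  }
  structure(list(left = left, right = right), class = "stereo_signal")
}

#' Synthetic-head configuration
#'
#' Parameters of the modal transcranial-path generator. The defaults describe
#' a plausible bone-conduction geometry at a 16 kHz working rate: the
#' ipsilateral (secondary) path h_LL arrives after 0.1 ms, the contralateral
#' (primary, crosstalk) path h_RL after 0.4 ms and 10 dB weaker (transcranial
#' attenuation), both built from 6 damped skull resonances in 200-3000 Hz with
#' 1-5 ms decay constants. Sensor recordings add Gaussian noise at
#' `sensor_noise_db` (dB re 1 V RMS).
#'
#' @param rate_hz Sampling rate (default 16000).
#' @param primary_delay_ms Crosstalk-path delay in ms (default 0.4).
#' @param secondary_delay_ms Ipsilateral-path delay in ms (default 0.1).
#' @param transcranial_attenuation_db Energy deficit of the primary relative
#'   to the secondary path in dB (default 10).
#' @param n_modes Number of damped resonances per path (default 6).
#' @param mode_band_hz Two-element range the mode frequencies are drawn from
#'   (default `c(200, 3000)`).
#' @param sensor_noise_db Additive recording-noise level (default -90).
#' @param n_taps Path length in samples (default 512, i.e. 32 ms).
#' @param seed Integer seed.
#' @return A `head_config` object.
#' @export
head_config <- function(rate_hz = 16000, primary_delay_ms = 0.4,
                        secondary_delay_ms = 0.1,
                        transcranial_attenuation_db = 10, n_modes = 6L,
                        mode_band_hz = c(200, 3000), sensor_noise_db = -90,
                        n_taps = 512L, seed = 1L) {
  if (primary_delay_ms < 0 || secondary_delay_ms < 0) {
    stop("delays must be >= 0", call. = FALSE)
  }
  if (secondary_delay_ms > primary_delay_ms) {
    stop("secondary (ipsilateral) delay must not exceed the primary delay",
         call. = FALSE)
  }
  if (n_modes < 1L) stop("`n_modes` must be >= 1", call. = FALSE)
  check_band(mode_band_hz[1], mode_band_hz[2], rate_hz)
  structure(list(rate_hz = rate_hz, primary_delay_ms = primary_delay_ms,
                 secondary_delay_ms = secondary_delay_ms,
                 transcranial_attenuation_db = transcranial_attenuation_db,
                 n_modes = as.integer(n_modes), mode_band_hz = mode_band_hz,
                 sensor_noise_db = sensor_noise_db,
                 n_taps = as.integer(n_taps), seed = as.integer(seed)),
            class = "head_config")
}

# One causal modal response: sum of damped sinusoids starting at `delay`
# samples, truncated to n_taps.
modal_response <- function(n_taps, rate_hz, delay_samples, freqs, decays_s,
                           phases, amps) {
  h <- numeric(n_taps)
  n_active <- n_taps - delay_samples
  if (n_active <= 0) stop("path delay exceeds the tap budget", call. = FALSE)
  t <- (seq_len(n_active) - 1L) / rate_hz
  for (i in seq_along(freqs)) {
    h[(delay_samples + 1L):n_taps] <- h[(delay_samples + 1L):n_taps] +
      amps[i] * exp(-t / decays_s[i]) * sin(2 * pi * freqs[i] * t + phases[i])
  }
  h
}

#' Generate a primary/secondary transfer-path pair
#'
#' Draws one set of skull modes (frequencies, decay constants, phases) under
#' the config seed, shared by both paths as common cranial resonances; each
#' path applies its own delay and a mild per-mode amplitude perturbation, and
#' the primary (crosstalk) path is rescaled so that its broadband energy sits
#' exactly `transcranial_attenuation_db` below the secondary's.
#'
#' @param config A [head_config()].
#' @return A `path_pair`: list with `h_primary` (h_RL, contralateral
#'   transducer to sensor), `h_secondary` (h_LL, ipsilateral transducer to
#'   sensor), both `time_signal`s of `n_taps` samples, and `rate_hz`.
#' @export
generate_paths <- function(config) {
  stopifnot(inherits(config, "head_config"))
  rate <- config$rate_hz
  d_pri <- round(config$primary_delay_ms * rate / 1000)
  d_sec <- round(config$secondary_delay_ms * rate / 1000)
  pars <- with_seed(config$seed, {
    list(freqs = stats::runif(config$n_modes, config$mode_band_hz[1],
                              config$mode_band_hz[2]),
         decays = stats::runif(config$n_modes, 1e-3, 5e-3),
         phases = stats::runif(config$n_modes, 0, 2 * pi),
         amps = stats::runif(config$n_modes, 0.5, 1),
         jitter_pri = stats::runif(config$n_modes, 0.8, 1.2),
         jitter_sec = stats::runif(config$n_modes, 0.8, 1.2))
  })
  h_sec <- modal_response(config$n_taps, rate, d_sec, pars$freqs, pars$decays,
                          pars$phases, pars$amps * pars$jitter_sec)
  h_pri <- modal_response(config$n_taps, rate, d_pri, pars$freqs, pars$decays,
                          pars$phases, pars$amps * pars$jitter_pri)
  h_sec <- h_sec / sqrt(sum(h_sec^2))
  h_pri <- h_pri / sqrt(sum(h_pri^2)) *
    10^(-config$transcranial_attenuation_db / 20)
  structure(list(h_primary = time_signal(h_pri, rate),
                 h_secondary = time_signal(h_sec, rate),
                 rate_hz = rate),
            class = "path_pair")
}

#' @export
print.path_pair <- function(x, ...) {
  cat(sprintf("<path_pair: %d taps @ %g Hz, primary/secondary energy ratio %.2f dB>\n",
              length(x$h_primary$samples), x$rate_hz,
              10 * log10(sum(x$h_primary$samples^2) /
                           sum(x$h_secondary$samples^2))))
  invisible(x)
}

#' Synthetic audiometric bone-transducer response
#'
#' A B81-like fixture: band-limited 200-4000 Hz (4th-order Butterworth
#' bandpass) with two fixed mechanical resonances, plus a small seeded FIR
#' perturbation bounded so that any two seeds differ by well under 1.5 dB in
#' magnitude response. Peak-normalized, 512 taps.
#'
#' @param label Text label carried on the object (e.g. "left").
#' @param seed Integer seed for the perturbation.
#' @param rate_hz Sampling rate (default 16000).
#' @return A `transducer_model`: list with `ir` (`time_signal`) and `label`.
#' @export
generate_transducer <- function(label, seed, rate_hz = 16000) {
  n_taps <- 512L
  imp <- c(1, numeric(n_taps - 1L))
  ba <- signal::butter(4L, c(200, 4000) * 2 / rate_hz, type = "pass")
  base <- as.numeric(signal::filter(ba, imp))
  # two mechanical resonances added in parallel: mild peaks (a few dB) on the
  # band-limited base, keeping the in-band dynamic range moderate so that a
  # regularized inverse can flatten it
  t <- (seq_len(n_taps) - 1L) / rate_hz
  res <- 0.9 * exp(-t / 3e-3) * sin(2 * pi * 700 * t) +
    0.6 * exp(-t / 1.5e-3) * sin(2 * pi * 2500 * t)
  base <- base + as.numeric(signal::filter(ba, res)) / 20
  g <- with_seed(seed, stats::rnorm(64L))
  g <- g * (0.05 / sum(abs(g)))  # |G(w)| <= 0.05 -> magnitude shift < 0.45 dB
  pert <- conv_full(base, c(1, g))[seq_len(n_taps)]
  pert <- pert / max(abs(pert))
  structure(list(ir = time_signal(pert, rate_hz), label = as.character(label)),
            class = "transducer_model")
}

#' Left/right transducer fixture pair
#'
#' @param seed Base seed; left uses `seed`, right `seed + 1`.
#' @param rate_hz Sampling rate (default 16000).
#' @return List with `left` and `right` `transducer_model`s whose magnitude
#'   responses differ by less than 1.5 dB across 200-4000 Hz.
#' @export
generate_transducer_pair <- function(seed, rate_hz = 16000) {
  list(left = generate_transducer("left", seed, rate_hz),
       right = generate_transducer("right", seed + 1L, rate_hz))
}

#' Simulate a sensor recording through the head
#'
#' The error-sensor signal for a stereo drive: the right channel travels the
#' primary (crosstalk) path, the left channel the secondary path, and seeded
#' Gaussian sensor noise is added at `sensor_noise_db`.
#'
#' @param paths A `path_pair` from [generate_paths()].
#' @param stereo A [stereo_signal()] at the same rate.
#' @param sensor_noise_db Noise level in dB re 1 V RMS (use e.g. -200 for an
#'   effectively noiseless sensor).
#' @param seed Integer seed for the noise.
#' @return A `time_signal` of `input length + path length - 1` samples.
#' @export
simulate_measurement <- function(paths, stereo, sensor_noise_db, seed) {
  stopifnot(inherits(paths, "path_pair"), inherits(stereo, "stereo_signal"))
  if (!isTRUE(all.equal(paths$rate_hz, stereo$left$rate_hz))) {
    stop("sampling rates of paths and stereo signal differ", call. = FALSE)
  }
  y <- conv_full(stereo$right$samples, paths$h_primary$samples) +
    conv_full(stereo$left$samples, paths$h_secondary$samples)
  noise <- with_seed(seed, stats::rnorm(length(y))) * 10^(sensor_noise_db / 20)
  time_signal(y + noise, paths$rate_hz)
}

#' Measure head paths with staggered TSP sweeps
#'
#' The full swept-sine measurement pipeline run in simulation: a stereo buffer
#' with the left-channel sweep starting at `onset_left_s` and the right at
#' `onset_right_s` (defaults 1 s and 5.1 s, i.e. staggered by just over the
#' 2.05 s sweep), played through the head, high-pass filtered at 100 Hz,
#' deconvolved with the inverse sweep, and sliced into two 512-tap responses.
#'
#' @param paths A `path_pair` (the ground truth being measured).
#' @param tsp A `tsp_pair` at the path rate (default: the 32728-sample sweep).
#' @param level_db Playback level of each sweep, dB re 1 V RMS (default -20).
#' @param onset_left_s,onset_right_s Sweep onsets in seconds.
#' @param sensor_noise_db Recording noise level (default from a quiet sensor,
#'   -120).
#' @param seed Seed for the sensor noise.
#' @param n_taps Extracted response length (default 512).
#' @param highpass_hz Cutoff of the pre-deconvolution high-pass applied to the
#'   recording (default 100 Hz, the measurement-protocol value); `NULL`
#'   disables it. Note that with the high-pass in place the recovered
#'   responses are, by construction, band-limited above the cutoff.
#' @return List with `h_primary` and `h_secondary` estimates (`time_signal`s)
#'   in the same orientation as [generate_paths()].
#' @export
measure_paths_tsp <- function(paths, tsp = NULL, level_db = -20,
                              onset_left_s = 1, onset_right_s = 5.1,
                              sensor_noise_db = -120, seed = 1L,
                              n_taps = 512L, highpass_hz = 100) {
  stopifnot(inherits(paths, "path_pair"))
  rate <- paths$rate_hz
  if (is.null(tsp)) tsp <- generate_tsp(32728L, rate_hz = rate)
  gain <- 10^(level_db / 20) / rms(tsp$sweep)  # sweep RMS -> level_db
  sweep <- tsp$sweep$samples * gain
  n_sweep <- length(sweep)
  o_l <- round(onset_left_s * rate)
  o_r <- round(onset_right_s * rate)
  n_buf <- max(o_l, o_r) + n_sweep + rate  # 1 s tail
  left <- numeric(n_buf); right <- numeric(n_buf)
  left[(o_l + 1L):(o_l + n_sweep)] <- sweep
  right[(o_r + 1L):(o_r + n_sweep)] <- sweep
  stereo <- stereo_signal(time_signal(left, rate), time_signal(right, rate))
  rec <- simulate_measurement(paths, stereo, sensor_noise_db, seed)
  if (!is.null(highpass_hz)) rec <- highpass(rec, highpass_hz)
  dec <- deconvolve(rec, tsp$inverse)
  h_sec <- extract_ir(dec, o_l + tsp$delay + 1L, n_taps)
  h_pri <- extract_ir(dec, o_r + tsp$delay + 1L, n_taps)
  list(h_primary = time_signal(h_pri$samples / gain, rate),
       h_secondary = time_signal(h_sec$samples / gain, rate))
}
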