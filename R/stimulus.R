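#' Raised-cosine (cos^2) fade-in/fade-out envelope
#'
#' @param n Total length in samples.
#' @param n_fade Ramp length in samples at each end.
#' @return Numeric envelope in `[0, 1]`.
#' @keywords internal
raised_cosine_envelope <- function(n, n_fade) {
  n <- as.integer(n); n_fade <- as.integer(n_fade)
  if (2L * n_fade > n) stop("fades longer than the signal", call. = FALSE)
  env <- rep(1, n)
  if (n_fade > 0L) {
    ramp <- sin(pi / 2 * seq_len(n_fade) / n_fade)^2
    env[seq_len(n_fade)] <- ramp
    env[(n - n_fade + 1L):n] <- rev(ramp)
  }
  env
}

#' Assemble a three-interval forced-choice stimulus
#'
#' Builds the masked tone-detection stimulus of the subjective evaluation:
#' three 800 ms intervals of one-third-octave band noise centered at the probe
#' frequency, one of which (chosen uniformly at random under `seed`) also
#' carries a 500 ms probe tone temporally centered in the noise (onset at
#' 150 ms). Both tone and masker have 75 ms raised-cosine fades. The tone
#' segment is scaled so its RMS sits exactly at `probe_level_db`; the masker
#' RMS sits at `masker_level_db`.
#'
#' @param probe_freq_hz Probe tone frequency in Hz (the evaluation uses
#'   250, 315, 397, 500, 630, 794 and 1000 Hz; any positive value is
#'   accepted).
#' @param probe_level_db Tone level, dB re 1 V RMS.
#' @param masker_level_db Masker level, dB re 1 V RMS.
#' @param rate_hz Sampling rate in Hz.
#' @param seed Integer seed (target interval and the three noise tokens).
#' @param masker_s,tone_s,fade_s,tone_onset_s Timing parameters in seconds;
#'   defaults are the protocol values (0.8, 0.5, 0.075, and centered onset
#'   (masker_s - tone_s)/2 = 0.15).
#' @return An `ifc_stimulus`: list with `intervals` (list of three
#'   `time_signal`s), `target_interval` (1, 2 or 3), `probe_freq_hz`,
#'   `probe_level_db`, `masker_level_db`.
#' @export
build_3ifc_stimulus <- function(probe_freq_hz, probe_level_db, masker_level_db,
                                rate_hz, seed,
                                masker_s = 0.8, tone_s = 0.5, fade_s = 0.075,
                                tone_onset_s = (masker_s - tone_s) / 2) {
  if (probe_freq_hz <= 0) stop("`probe_freq_hz` must be positive", call. = FALSE)
  if (!all(is.finite(c(probe_level_db, masker_level_db)))) {
    stop("levels must be finite", call. = FALSE)
  }
  n_mask <- round(masker_s * rate_hz)
  n_tone <- round(tone_s * rate_hz)
  n_fade <- round(fade_s * rate_hz)
  onset <- round(tone_onset_s * rate_hz)
  band <- third_octave_band(probe_freq_hz)

  with_seed(seed, {
    target <- sample.int(3L, 1L)
    noise_seeds <- sample.int(.Machine$integer.max, 3L)
  })

  tone <- sin(2 * pi * probe_freq_hz * (seq_len(n_tone) - 1L) / rate_hz) *
    raised_cosine_envelope(n_tone, n_fade)
  tone <- tone * (10^(probe_level_db / 20) / sqrt(mean(tone^2)))

  intervals <- lapply(1:3, function(i) {
    masker <- bandpass_noise(rate_hz, n_mask / rate_hz,
                             band[["f_lo_hz"]], band[["f_hi_hz"]],
                             seed = noise_seeds[i])$samples
    masker <- masker * raised_cosine_envelope(n_mask, n_fade)
    masker <- masker * (10^(masker_level_db / 20) / sqrt(mean(masker^2)))
    if (i == target) {
      masker[(onset + 1L):(onset + n_tone)] <-
        masker[(onset + 1L):(onset + n_tone)] + tone
    }
    time_signal(masker, rate_hz)
  })

  structure(list(intervals = intervals, target_interval = target,
                 probe_freq_hz = probe_freq_hz,
                 probe_level_db = probe_level_db,
                 masker_level_db = masker_level_db),
            class = "ifc_stimulus")
}

#' @export
print.ifc_stimulus <- function(x, ...) {
  cat(sprintf("<ifc_stimulus: %g Hz probe at %.1f dB in interval %d, masker %.1f dB>\n",
              x$probe_freq_hz, x$probe_level_db, x$target_interval,
              x$masker_level_db))
  invisible(x)
}
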