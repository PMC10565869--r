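#' Measure crosstalk reduction at the error sensor
#'
#' Reproduces the verification experiment in simulation: a band-limited noise
#' probe is played through the (virtual) right transducer, and the sensor
#' signal is compared without and with the anti-noise generated by the CTC
#' filter on the left transducer:
#' `without = noise * h_RL`, `with = noise * h_RL + (noise * w) * h_LL`.
#' Levels are band-limited RMS over the steady-state window (the first and
#' last 100 ms are excluded) in dB re 1 V RMS; the broadband in-band reduction
#' and the per-third-octave reductions at the seven evaluation centers inside
#' the band are reported.
#'
#' @param paths A `path_pair`.
#' @param ctc A `ctc_filter`.
#' @param noise_duration_s Probe duration in seconds (default 6, the
#'   verification-protocol value).
#' @param band Passband of the probe noise in Hz (default `c(224, 1122)`).
#' @param seed Seed for the probe noise.
#' @param edge_s Steady-state edge exclusion in seconds (default 0.1).
#' @return A `reduction_report`: list with `level_without_db`,
#'   `level_with_db`, `reduction_db` (= without - with, exactly),
#'   `broadband_reduction_db` (same comparison without band filtering),
#'   `band`, and `per_third_octave` (tibble `center_hz`, `reduction_db`).
#' @export
measure_reduction <- function(paths, ctc, noise_duration_s = 6,
                              band = c(224, 1122), seed = 1L, edge_s = 0.1) {
  stopifnot(inherits(paths, "path_pair"), inherits(ctc, "ctc_filter"))
  if (!isTRUE(all.equal(paths$rate_hz, ctc$rate_hz))) {
    stop("sampling rates of paths and CTC filter differ", call. = FALSE)
  }
  rate <- paths$rate_hz
  check_band(band[1], band[2], rate)
  noise <- bandpass_noise(rate, noise_duration_s, band[1], band[2], seed = seed)
  without <- conv_full(noise$samples, paths$h_primary$samples)
  anti <- conv_full(conv_full(noise$samples, ctc$taps),
                    paths$h_secondary$samples)
  n <- max(length(without), length(anti))
  without <- c(without, numeric(n - length(without)))
  with_ <- without + c(anti, numeric(n - length(anti)))
  sig_wo <- time_signal(without, rate)
  sig_wi <- time_signal(with_, rate)

  lvl_wo <- band_level_db(sig_wo, band[1], band[2], edge_s = edge_s)
  lvl_wi <- band_level_db(sig_wi, band[1], band[2], edge_s = edge_s)

  centers <- probe_frequencies()
  centers <- centers[centers * 2^(1 / 6) <= band[2] * 2^(1 / 6) &
                       centers * 2^(-1 / 6) >= band[1] * 2^(-1 / 6)]
  per_band <- vapply(centers, function(fc) {
    b <- third_octave_band(fc)
    band_level_db(sig_wo, b[1], b[2], edge_s = edge_s) -
      band_level_db(sig_wi, b[1], b[2], edge_s = edge_s)
  }, numeric(1))

  structure(list(level_without_db = lvl_wo,
                 level_with_db = lvl_wi,
                 reduction_db = lvl_wo - lvl_wi,
                 broadband_reduction_db = level_db(sig_wo) - level_db(sig_wi),
                 band = band,
                 per_third_octave = tibble::tibble(center_hz = centers,
                                                   reduction_db = per_band)),
            class = "reduction_report")
}

#' @export
print.reduction_report <- function(x, ...) {
  cat(sprintf("<reduction_report: %.2f dB in %g-%g Hz (%.2f dB -> %.2f dB)>\n",
              x$reduction_db, x$band[1], x$band[2],
              x$level_without_db, x$level_with_db))
  print(x$per_third_octave)
  invisible(x)
}

#' Re-estimate the CTC filter if cancellation has degraded
#'
#' The recovery step of the verification protocol: if an existing filter no
#' longer achieves at least `threshold_db` of in-band reduction on the
#' (possibly shifted) current paths — e.g. after a transducer moved — the
#' filter is re-estimated on the new paths.
#'
#' @param paths_new Current `path_pair`.
#' @param ctc_old Previously estimated `ctc_filter`.
#' @param config [fxlms_config()] used for re-estimation.
#' @param threshold_db Minimum acceptable reduction (default 10 dB, the
#'   effectiveness criterion).
#' @param seed Seed for the verification noise.
#' @return List with `filter` (old or re-estimated `ctc_filter`), `report`
#'   (its `reduction_report` on `paths_new`), and `reestimated` (logical).
#' @export
reestimate_if_shifted <- function(paths_new, ctc_old, config = fxlms_config(),
                                  threshold_db = 10, seed = 1L) {
  report_old <- measure_reduction(paths_new, ctc_old, seed = seed)
  if (report_old$reduction_db >= threshold_db) {
    return(list(filter = ctc_old, report = report_old, reestimated = FALSE))
  }
  fit <- estimate_ctc_filter(paths_new, config)
  list(filter = fit$filter,
       report = measure_reduction(paths_new, fit$filter, seed = seed),
       reestimated = TRUE)
}
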