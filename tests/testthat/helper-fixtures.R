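# Shared fixtures, built once per test run. Everything is generated in code;
# seeds are fixed so every expectation below is deterministic.

fixture_rate <- 16000

# default synthetic head (the study conditions)
fixture_paths <- generate_paths(head_config(seed = 1))

# anti-symmetric head: the crosstalk path is exactly the negated secondary
# path, so the exact CTC solution is a unit impulse (in-band)
fixture_paths_antisym <- local({
  p <- fixture_paths
  p$h_primary <- time_signal(-p$h_secondary$samples, fixture_rate)
  p
})

# a short TSP pair for fast unit tests (full 32728-sample pair is exercised
# in the acceptance suite)
fixture_tsp_small <- generate_tsp(4096L, rate_hz = fixture_rate)

zero_ctc <- function(p = 512L, rate_hz = fixture_rate) {
  structure(list(taps = numeric(p), rate_hz = rate_hz), class = "ctc_filter")
}

rel_l2 <- function(got, want) {
  sqrt(sum((got - want)^2) / sum(want^2))
}

# in-band residual of a frozen CTC filter: level change (dB) in f_lo..f_hi of
# the sensor signal when the anti-noise is added
frozen_residual_db <- function(paths, ctc, f_lo = 250, f_hi = 1000,
                               seed = 9L, duration_s = 6) {
  noise <- bandpass_noise(paths$rate_hz, duration_s, seed = seed)
  wo <- conv_full(noise$samples, paths$h_primary$samples)
  anti <- conv_full(conv_full(noise$samples, ctc$taps),
                    paths$h_secondary$samples)
  n <- max(length(wo), length(anti))
  wo <- c(wo, numeric(n - length(wo)))
  wi <- wo + c(anti, numeric(n - length(anti)))
  band_level_db(time_signal(wi, paths$rate_hz), f_lo, f_hi) -
    band_level_db(time_signal(wo, paths$rate_hz), f_lo, f_hi)
}

conv_full <- ctcsim:::conv_full
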