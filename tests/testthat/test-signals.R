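test_that("time_signal validates its fields and carries the level convention", {
  expect_error(time_signal(numeric(0), 16000), "length")
  expect_error(time_signal(c(1, NA), 16000), "finite")
  expect_error(time_signal(1:4, -1), "positive")
  # unit-amplitude sine reads -3.0103 dB re 1 V RMS
  x <- time_signal(sin(2 * pi * 100 * (0:15999) / 16000), 16000)
  expect_equal(level_db(x), 20 * log10(1 / sqrt(2)), tolerance = 1e-4)
  expect_equal(level_db(set_level(x, -20)), -20, tolerance = 1e-12)
})

test_that("TSP pair has the printed duration, a flat spectrum and an exact circular inverse", {
  tsp <- generate_tsp(32728L, rate_hz = 16000)
  expect_equal(duration_s(tsp$sweep), 2.0455, tolerance = 1e-4)
  expect_equal(round(duration_s(tsp$sweep), 2), 2.05)
  expect_equal(duration_s(generate_tsp(32768L, rate_hz = 16000)$sweep), 2.048)

  # magnitude spectrum flat across all bins
  mag <- Mod(stats::fft(tsp$sweep$samples))
  expect_lt(max(mag[-1]) / min(mag[-1]), 1 + 1e-9)

  # circular convolution with the inverse is a unit impulse at lag 0
  n <- tsp$n_samples
  circ <- Re(stats::fft(stats::fft(tsp$sweep$samples) *
                          stats::fft(tsp$inverse$samples), inverse = TRUE)) / n
  expect_equal(which.max(abs(circ)), 1L)
  expect_lt((sum(circ^2) - circ[1]^2) / circ[1]^2, 1e-10)

  expect_equal(max(abs(tsp$sweep$samples)), 1)
  expect_error(generate_tsp(-4, rate_hz = 16000), "positive")
  expect_error(generate_tsp(4097L, rate_hz = 16000), "even")
  expect_error(generate_tsp(4096L, rate_hz = 0), "positive")
})

test_that("deconvolution recovers embedded impulse responses exactly", {
  tsp <- fixture_tsp_small
  # sweep through identity -> impulse at the sweep onset (offset 0)
  dec0 <- deconvolve(tsp$sweep, tsp$inverse)
  expect_equal(which.max(abs(dec0$samples)), 1L + tsp$delay)
  expect_equal(dec0$samples[1L + tsp$delay], 1, tolerance = 1e-9)

  # short known response
  h3 <- c(1, 0.5, 0.25)
  rec <- convolve_signals(tsp$sweep, time_signal(h3, fixture_rate))
  dec <- deconvolve(rec, tsp$inverse)
  expect_equal(dec$samples[1:3], h3, tolerance = 1e-6)

  # rate mismatch is rejected
  expect_error(deconvolve(time_signal(rnorm(8192), 8000), tsp$inverse),
               "rates differ")
})

test_that("TSP round trip holds for arbitrary long responses (property)", {
  tsp <- fixture_tsp_small
  for (s in 1:5) {
    h <- withr::with_seed(s, rnorm(512) * exp(-(0:511) / 80))
    rec <- convolve_signals(tsp$sweep, time_signal(h, fixture_rate))
    got <- deconvolve(rec, tsp$inverse)$samples[1:512]
    expect_lt(rel_l2(got, h), 1e-6)
  }
})

test_that("staggered sweeps in one recording deconvolve to separated responses", {
  tsp <- fixture_tsp_small
  rate <- fixture_rate
  h_a <- c(numeric(5), 1, 0.4)      # delayed response on the first sweep
  h_b <- c(numeric(2), -0.8, 0.3)   # different response on the second
  o1 <- 1600L; o2 <- 8000L
  n <- o2 + 4096L + length(h_b) + 100L
  buf <- numeric(n)
  s1 <- conv_full(tsp$sweep$samples, h_a)
  s2 <- conv_full(tsp$sweep$samples, h_b)
  buf[o1 + seq_along(s1)] <- buf[o1 + seq_along(s1)] + s1
  buf[o2 + seq_along(s2)] <- buf[o2 + seq_along(s2)] + s2
  dec <- deconvolve(time_signal(buf, rate), tsp$inverse)
  expect_equal(dec$samples[o1 + seq_along(h_a)], h_a, tolerance = 1e-7)
  expect_equal(dec$samples[o2 + seq_along(h_b)], h_b, tolerance = 1e-7)
})

test_that("extract_ir slices exactly and rejects out-of-range requests", {
  x <- time_signal(seq_len(2000), fixture_rate)
  sl <- extract_ir(x, 101L, 512L)
  expect_equal(duration_s(sl), 0.032)            # 512 samples = 32 ms at 16 kHz
  expect_identical(sl$samples, as.numeric(101:612))
  expect_error(extract_ir(x, 1600L, 512L), "out of range")
  expect_error(extract_ir(x, 0L, 10L), "out of range")
})

test_that("onset heuristic finds a known path delay within tolerance", {
  d <- 37L
  h <- c(numeric(d), exp(-(0:200) / 30) * sin(2 * pi * 700 * (0:200) / 16000))
  onset <- find_ir_onset(time_signal(h, fixture_rate))
  expect_lte(abs(onset - (d + 1L)), 8L)
  expect_error(find_ir_onset(time_signal(numeric(10), 16000)), "all-zero")
})

test_that("bandpass noise is reproducible, in-band and unit-RMS", {
  a <- bandpass_noise(16000, 1, seed = 5)
  b <- bandpass_noise(16000, 1, seed = 5)
  expect_identical(a$samples, b$samples)
  expect_equal(rms(a), 1, tolerance = 1e-12)

  pg <- stats::spec.pgram(stats::ts(a$samples, frequency = 16000),
                          taper = 0, plot = FALSE)
  in_band <- sum(pg$spec[pg$freq >= 224 & pg$freq <= 1122]) / sum(pg$spec)
  expect_gt(in_band, 0.95)
  # the evaluation centers all lie inside the default band
  expect_true(all(c(250, 315, 397, 500, 630, 794, 1000) > 224 &
                    c(250, 315, 397, 500, 630, 794, 1000) < 1122))
  expect_error(bandpass_noise(16000, 1, f_lo_hz = 500, f_hi_hz = 400, seed = 1),
               "invalid band")
})

test_that("high-pass filter rejects DC, passes 1 kHz, attenuates 50 Hz", {
  dc <- time_signal(rep(1, 16000), fixture_rate)
  # steady-state DC rejection (the zero-phase filter rings briefly at the
  # sequence edges)
  expect_lt(rms(highpass(dc)$samples[2001:14000]), 1e-2 * rms(dc))

  tone <- time_signal(sin(2 * pi * 1000 * (0:15999) / 16000), fixture_rate)
  expect_lt(abs(rms(highpass(tone)) / rms(tone) - 1), 0.06)

  low <- time_signal(sin(2 * pi * 50 * (0:15999) / 16000), fixture_rate)
  expect_lt(20 * log10(rms(highpass(low)) / rms(low)), -20)
  expect_error(highpass(tone, cutoff_hz = 9000), "Nyquist")
})

test_that("third-octave band edges follow the base-2 definition", {
  b1000 <- third_octave_band(1000)
  expect_equal(unname(b1000), c(890.9, 1122.5), tolerance = 1e-4)
  b250 <- third_octave_band(250)
  expect_equal(unname(b250[1]), 222.7, tolerance = 1e-3)
  expect_equal(unname(b1000[2] / b1000[1]), 2^(1 / 3), tolerance = 1e-12)
  expect_error(third_octave_band(-10), "positive")
})

test_that("3IFC stimulus has protocol timing, exact tone level and a seeded target", {
  st <- build_3ifc_stimulus(1000, -20, -30, fixture_rate, seed = 11)
  expect_length(st$intervals, 3L)
  expect_true(all(vapply(st$intervals, length, 1L) == 0.8 * fixture_rate))
  expect_true(st$target_interval %in% 1:3)

  # tone sits at 150 ms; with the masker pushed to the noise floor the target
  # segment is the tone alone, whose RMS must sit exactly at the probe level
  onset <- round(0.15 * fixture_rate)
  n_tone <- round(0.5 * fixture_rate)
  other <- st$intervals[[setdiff(1:3, st$target_interval)[1]]]$samples
  expect_equal(level_db(other), -30, tolerance = 1e-6)

  st_quiet <- build_3ifc_stimulus(1000, -20, -120, fixture_rate, seed = 11)
  tgt <- st_quiet$intervals[[st_quiet$target_interval]]$samples
  seg <- tgt[(onset + 1L):(onset + n_tone)]
  expect_equal(20 * log10(sqrt(mean(seg^2))), -20, tolerance = 0.1)
  # and the tone region is silent outside the 500 ms window
  expect_lt(level_db(tgt[1:onset]), -100)

  # reproducibility and target-interval distribution under different seeds
  st2 <- build_3ifc_stimulus(1000, -20, -30, fixture_rate, seed = 11)
  expect_identical(st$intervals[[1]]$samples, st2$intervals[[1]]$samples)
  targets <- vapply(1:30, function(s)
    build_3ifc_stimulus(500, -20, -30, fixture_rate, seed = s)$target_interval,
    1L)
  expect_setequal(unique(targets), 1:3)
})

test_that("target interval carries more energy than the others at equal levels (property)", {
  for (s in 1:20) {
    st <- build_3ifc_stimulus(500, -20, -20, fixture_rate, seed = s)
    en <- vapply(st$intervals, function(x) sum(x$samples^2), numeric(1))
    expect_gt(en[st$target_interval], max(en[-st$target_interval]))
  }
})

test_that("fade envelope rises over 75 ms as cos^2 on both tone and masker", {
  st <- build_3ifc_stimulus(1000, -20, -30, fixture_rate, seed = 3,
                            masker_s = 0.8, fade_s = 0.075)
  n_fade <- round(0.075 * fixture_rate)
  env <- ctcsim:::raised_cosine_envelope(round(0.8 * fixture_rate), n_fade)
  expect_equal(env[1], sin(pi / 2 / n_fade)^2)
  expect_equal(env[n_fade], 1)
  expect_equal(env[n_fade %/% 2L], 0.5, tolerance = 0.01)
  # masker amplitude in the first fade samples is attenuated accordingly
  m <- st$intervals[[setdiff(1:3, st$target_interval)[1]]]$samples
  early <- sqrt(mean(m[1:(n_fade %/% 4)]^2))
  steady <- sqrt(mean(m[(2 * n_fade):(3 * n_fade)]^2))
  expect_lt(early, 0.25 * steady)
})
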