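test_that("regularization profile evaluates to eps_min in band, eps_max outside", {
  pr <- reg_profile(eps_min = 1e-4, eps_max = 1, f_low_hz = 200,
                    f_high_hz = 4000, transition_octaves = 0.5)
  n <- 4096L
  eps <- regularization_vector(pr, n, 16000)
  expect_length(eps, n)
  f <- pmin(0:(n - 1L), n - 0:(n - 1L)) * 16000 / n
  # strictly inside the band
  expect_true(all(abs(eps[f >= 200 & f <= 4000] - 1e-4) < 1e-12))
  # DC and far outside
  expect_equal(eps[1], 1)
  expect_true(all(eps[f > 0 & f <= 200 / 2^0.5 - 1] == 1))
  # Hermitian layout: bin k and n-k agree
  expect_equal(eps[2:100], eps[n - (0:98)])
  # monotone non-increasing through the lower transition
  grid <- 2^seq(log2(100), log2(200), length.out = 64)
  vals <- vapply(grid, function(ff) {
    nn <- 8192L
    k <- round(ff * nn / 16000)
    regularization_vector(pr, nn, 16000)[k + 1L]
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  expect_error(regularization_vector(reg_profile(f_high_hz = 9000), 512, 16000),
               "Nyquist")
})

test_that("Kirkeby inverse of an impulse is a delayed impulse; zero regularization is exact", {
  delta_ir <- time_signal(c(1, numeric(255)), 16000)
  pr0 <- reg_profile(eps_min = 0, eps_max = 1e-14)
  eq <- kirkeby_inverse(delta_ir, pr0, n_fft = 1024L, modeling_delay = 100L)
  expect_equal(which.max(abs(eq$taps)), 101L)
  expect_equal(eq$taps[101], 1, tolerance = 1e-9)
  expect_lt(max(abs(eq$taps[-101])), 1e-9)

  # |C * T| = 1 at every bin for an invertible minimum-phase response
  mp <- time_signal(c(1, 0.5, numeric(254)), 16000)
  eqm <- kirkeby_inverse(mp, pr0, n_fft = 1024L, modeling_delay = 0L)
  Tw <- stats::fft(c(mp$samples, numeric(1024 - 256)))
  Cw <- stats::fft(c(eqm$taps))
  expect_lt(max(abs(Mod(Cw * Tw) - 1)), 1e-9)

  expect_error(kirkeby_inverse(time_signal(numeric(64), 16000),
                               reg_profile(eps_min = 0), n_fft = 256L),
               "singular")
  expect_error(kirkeby_inverse(delta_ir, reg_profile(), n_fft = 300L), "twice")
})

test_that("equalizing the synthetic transducer flattens its response below 2 dB ripple", {
  pair <- generate_transducer_pair(11)
  pr <- reg_profile()
  eq <- kirkeby_inverse(pair$left$ir, pr)
  eqd <- apply_equalization(pair$left$ir, eq)
  expect_lt(flatness_metric(eqd, 200, 4000), 2)
  # unequalized response is materially less flat
  expect_gt(flatness_metric(pair$left$ir, 200, 4000),
            flatness_metric(eqd, 200, 4000) + 2)

  # the left filter applied to the right transducer (pair differs < 1.5 dB)
  # degrades ripple by less than 1.5 dB
  eqx <- apply_equalization(pair$right$ir, eq)
  expect_lt(flatness_metric(eqx, 200, 4000),
            flatness_metric(eqd, 200, 4000) + 1.5)
})

test_that("apply_equalization is a full linear convolution with rate checking", {
  ir <- time_signal(c(0.2, 1, -0.3), 16000)
  eqd <- structure(list(taps = c(numeric(10), 1), rate_hz = 16000,
                        modeling_delay = 10L), class = "eq_filter")
  out <- apply_equalization(ir, eqd)
  expect_length(out$samples, 3 + 11 - 1)
  expect_equal(out$samples[11:13], ir$samples)
  bad <- structure(list(taps = 1, rate_hz = 8000, modeling_delay = 0L),
                   class = "eq_filter")
  expect_error(apply_equalization(ir, bad), "rates differ")
})

test_that("energy bound |C| <= 1/(2 sqrt(eps)) holds at every bin", {
  pair <- generate_transducer_pair(4)
  pr <- reg_profile(eps_min = 1e-3, eps_max = 0.5)
  n_fft <- 4096L
  eq <- kirkeby_inverse(pair$left$ir, pr, n_fft = n_fft)
  Tw <- stats::fft(c(pair$left$ir$samples, numeric(n_fft - 512)))
  eps <- regularization_vector(pr, n_fft, 16000) * max(Mod(Tw)^2)
  Cw <- Mod(stats::fft(eq$taps))
  expect_true(all(Cw <= 1 / (2 * sqrt(eps)) + 1e-9))
})

test_that("regularized inverse converges monotonically to the exact inverse as eps shrinks", {
  mp <- time_signal(c(1, 0.4, 0.2, numeric(253)), 16000)
  n_fft <- 1024L
  Tw <- stats::fft(c(mp$samples, numeric(n_fft - 256)))
  dev <- vapply(c(1e-2, 1e-4, 1e-6, 1e-8), function(e) {
    eq <- kirkeby_inverse(mp, reg_profile(eps_min = e, eps_max = e * 1.0001),
                          n_fft = n_fft, modeling_delay = 0L)
    max(abs(Mod(stats::fft(eq$taps) * Tw) - 1))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[4], 1e-6)
})

test_that("the Kirkeby filter compensates an input delay exactly", {
  pair <- generate_transducer_pair(7)
  ir <- pair$left$ir
  d <- 16L
  ir_delayed <- time_signal(c(numeric(d), ir$samples[1:(512 - d)]), 16000)
  pr <- reg_profile()
  e1 <- apply_equalization(ir, kirkeby_inverse(ir, pr))
  e2 <- apply_equalization(ir_delayed, kirkeby_inverse(ir_delayed, pr))
  # the inverse acquires a matching advance, so the equalized response is
  # unshifted (up to the shared modeling delay)
  win <- 1500:4000
  expect_lt(rel_l2(e2$samples[win], e1$samples[win]), 1e-3)
})

test_that("flatness metric is zero for an impulse and matches a one-pole roll-off", {
  expect_equal(flatness_metric(time_signal(c(1, numeric(127)), 16000),
                               500, 2000), 0, tolerance = 1e-9)
  # single-pole low-pass with 3 dB point at 1 kHz: about 3 dB over the
  # octave straddling it (707-1414 Hz)
  a <- exp(-2 * pi * 1000 / 16000)
  h <- (1 - a) * a^(0:511)
  fm <- flatness_metric(time_signal(h, 16000), 1000 / sqrt(2), 1000 * sqrt(2))
  expect_equal(fm, 3, tolerance = 0.8)
  expect_error(flatness_metric(time_signal(c(1, numeric(127)), 16000),
                               3000, 2000), "invalid band")
})
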