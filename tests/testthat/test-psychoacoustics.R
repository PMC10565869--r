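test_that("staircase follows the transformed up-down rules step by step", {
  cfg <- staircase_config()
  tr <- staircase_track(cfg)
  # one incorrect response raises the level by the large step, no reversal
  tr1 <- staircase_update(tr, FALSE, cfg)
  expect_equal(tr1$level_db, -20 + 4)
  expect_length(tr1$reversal_levels, 0L)
  # a single correct response does not move the level (2-down)
  tr2 <- staircase_update(staircase_track(cfg), TRUE, cfg)
  expect_equal(tr2$level_db, -20)
  # two consecutive correct responses lower it
  tr3 <- staircase_update(tr2, TRUE, cfg)
  expect_equal(tr3$level_db, -24)
  expect_equal(nrow(tr3$trials), 2L)
})

test_that("a hand-simulated alternating track reproduces the enumerated reversals and threshold", {
  # responses: CC W CC W ... CC (7 double-correct runs, 6 singles incorrect)
  # hand enumeration: first move -4 (no reversal), then every move reverses;
  # step drops to 2 dB after the 4th reversal; reversal levels are
  # -24,-20,-24,-20, -24,-22,-24,-22,-24,-22,-24,-22 and the mean of the last
  # eight is -23.
  responses <- unlist(lapply(1:13, function(i)
    if (i %% 2 == 1) c(TRUE, TRUE) else FALSE))
  cfg <- staircase_config()
  tr <- staircase_track(cfg)
  for (r in responses) {
    if (tr$finished) break
    tr <- staircase_update(tr, r, cfg)
  }
  expect_true(tr$finished)
  expect_equal(tr$reversal_levels,
               c(-24, -20, -24, -20, -24, -22, -24, -22, -24, -22, -24, -22))
  expect_identical(tr$threshold_db, -23)
  expect_identical(tr$threshold_db,
                   mean(utils::tail(tr$reversal_levels, 8)))
  expect_error(staircase_update(tr, TRUE, cfg), "finished")
})

test_that("threshold equals the exact mean of the last eight reversal levels", {
  tr <- run_staircase(sim_listener(-50, 1, seed = 1), staircase_config(),
                      seed = 7)
  expect_true(tr$finished)
  expect_length(tr$reversal_levels, 12L)
  expect_identical(tr$threshold_db, mean(utils::tail(tr$reversal_levels, 8)))
  # re-derive the reversal levels from the trial log
  log_rev <- tr$trials$level_db[tr$trials$is_reversal]
  expect_identical(log_rev, tr$reversal_levels)
})

test_that("simulated responses follow the psychometric function", {
  li <- sim_listener(-50, slope_db = 2, seed = 3)
  # midpoint: p = 1/3 + (2/3) * 0.5 = 2/3
  expect_equal(ctcsim:::p_correct(li, -50), 2 / 3)
  # ceiling far above threshold
  expect_true(simulate_response(li, 0, 1))
  # determinism in (seed, trial)
  expect_identical(simulate_response(li, -50, 42),
                   simulate_response(li, -50, 42))
  # empirical proportion over 10000 trials at a fixed level
  lvl <- -49
  p_want <- ctcsim:::p_correct(li, lvl)
  hits <- sum(vapply(1:10000, function(i) simulate_response(li, lvl, i),
                     logical(1)))
  expect_lt(abs(hits / 10000 - p_want), 0.015)
})

test_that("staircase estimates the 70.7 percent point of a steep listener", {
  li <- sim_listener(-50, slope_db = 0.5, seed = 1)
  target <- staircase_target_level(li)
  # the 2-down/1-up equilibrium is the p = sqrt(1/2) level
  expect_equal(ctcsim:::p_correct(li, target), sqrt(0.5), tolerance = 1e-9)
  ths <- vapply(1:50, function(s)
    run_staircase(li, staircase_config(), seed = s)$threshold_db, numeric(1))
  expect_lt(abs(mean(ths) - target), 1)
  # identical inputs give identical tracks
  t1 <- run_staircase(li, staircase_config(), seed = 12)
  t2 <- run_staircase(li, staircase_config(), seed = 12)
  expect_identical(t1$trials, t2$trials)
})

test_that("bias stays bounded for moderate slopes and lapse rates (property)", {
  li <- sim_listener(-45, slope_db = 2, lapse_rate = 0.02, seed = 1)
  target <- staircase_target_level(li)
  ths <- vapply(1:60, function(s)
    run_staircase(li, staircase_config(), seed = 1000 + s)$threshold_db,
    numeric(1))
  expect_lt(abs(mean(ths) - target), 2)
})

test_that("an always-correct listener descends monotonically until the trial cap", {
  li <- sim_listener(-Inf, slope_db = 1, seed = 1)
  err <- tryCatch(run_staircase(li, staircase_config(), seed = 1,
                                max_trials = 60L),
                  ctcsim_nonconvergence = function(e) e)
  expect_s3_class(err, "ctcsim_nonconvergence")
  lv <- err$track$trials$level_db
  expect_true(all(diff(lv) <= 0))
  expect_length(err$track$reversal_levels, 0L)
})

test_that("bracketing recovers a step-function listener on the 5 dB grid", {
  li <- sim_listener(-42, slope_db = 1e-6, seed = 2)
  th <- run_bracketing(li, bracketing_config(),
                       freqs_hz = c(250, 500, 1000, 2000, 4000), seed = 3)
  # threshold -42 is detected from -40 upward; grid rounds up to -40
  expect_true(all(th == -40))
  # frequency order: 1000 Hz first, then ascending
  expect_identical(names(th), c("1000", "250", "500", "2000", "4000"))
  # all outputs on the 5 dB grid anchored at the start level
  expect_true(all((th - 30) %% 5 == 0))
})

test_that("a listener who hears everything bottoms out at the lowest probed level", {
  li <- sim_listener(-1e6, slope_db = 1e-6, seed = 1)
  th <- run_bracketing(li, bracketing_config(), freqs_hz = 1000, seed = 1,
                       max_presentations = 25L)
  expect_equal(unname(th), 30 - 24 * 10)
})

test_that("threshold improvement is the plain difference with the documented sign", {
  expect_equal(threshold_improvement(-50.75, -65), 14.25)
  expect_equal(threshold_improvement(-40, -40), 0)
  expect_equal(threshold_improvement(-40, -45),
               -threshold_improvement(-45, -40))
  expect_error(threshold_improvement(NA, -3), "finite")
})

test_that("occlusion effect compares audiograms frequency by frequency", {
  un <- c("250" = -30, "500" = -35, "1000" = -40, "2000" = -40, "4000" = -35)
  expect_true(all(occlusion_effect(un, un) == 0))
  oc <- un; oc["250"] <- un["250"] - 15
  eff <- occlusion_effect(oc, un)
  expect_equal(unname(eff["250"]), 15)
  expect_true(all(eff[c("500", "1000", "2000", "4000")] == 0))
  expect_error(occlusion_effect(oc[-1], un), "keys")

  # end-to-end through bracketing: a 15 dB low-frequency shift is recovered
  # within the 5 dB grid resolution
  li_un <- sim_listener(un, slope_db = 1e-6, seed = 4)
  li_oc <- sim_listener(oc, slope_db = 1e-6, seed = 5)
  th_un <- run_bracketing(li_un, seed = 11)
  th_oc <- run_bracketing(li_oc, seed = 12)
  eff2 <- occlusion_effect(th_oc, th_un)
  expect_lte(abs(eff2[["250"]] - 15), 5)
})
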