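#' Adaptive-staircase settings
#'
#' Configuration of the transformed up-down (2-down/1-up) three-interval
#' forced-choice procedure used for masked-threshold measurement: start at
#' -20 dB re 1 V RMS, 4 dB steps until the fourth reversal, 2 dB thereafter,
#' stop at 12 reversals, threshold = mean of the last 8 reversal levels.
#'
#' @param initial_level_db Starting probe level (default -20).
#' @param step_large_db Step size before the switch (default 4).
#' @param step_small_db Step size after the switch (default 2).
#' @param reversals_to_small_step Reversal count after which the small step
#'   applies (default 4).
#' @param total_reversals Reversals at which the track finishes (default 12).
#' @param reversals_averaged Trailing reversals averaged into the threshold
#'   (default 8).
#' @param n_intervals Number of forced-choice intervals (default 3).
#' @param down_rule Consecutive correct responses required to step down
#'   (default 2).
#' @param up_rule Incorrect responses required to step up (default 1).
#' @return A `staircase_config` object.
#' @export
staircase_config <- function(initial_level_db = -20, step_large_db = 4,
                             step_small_db = 2, reversals_to_small_step = 4L,
                             total_reversals = 12L, reversals_averaged = 8L,
                             n_intervals = 3L, down_rule = 2L, up_rule = 1L) {
  if (step_large_db <= 0 || step_small_db <= 0) {
    stop("step sizes must be > 0", call. = FALSE)
  }
  if (reversals_averaged > total_reversals) {
    stop("`reversals_averaged` must not exceed `total_reversals`", call. = FALSE)
  }
  structure(list(initial_level_db = initial_level_db,
                 step_large_db = step_large_db, step_small_db = step_small_db,
                 reversals_to_small_step = as.integer(reversals_to_small_step),
                 total_reversals = as.integer(total_reversals),
                 reversals_averaged = as.integer(reversals_averaged),
                 n_intervals = as.integer(n_intervals),
                 down_rule = as.integer(down_rule),
                 up_rule = as.integer(up_rule)),
            class = "staircase_config")
}

#' Simulated listener
#'
#' A standard psychometric observer standing in for a human participant:
#' probability of a correct response at probe level L is
#' `p(L) = guess + (1 - guess - lapse) * logistic((L - threshold) / slope)`,
#' so at `L = true_threshold_db` the observer scores midway between guessing
#' and ceiling (2/3 for a 3IFC task at zero lapse).
#'
#' @param true_threshold_db Psychometric midpoint in dB re 1 V RMS. May be a
#'   named vector keyed by frequency (as `"250"`, `"1000"`, ...) for
#'   audiometric simulations.
#' @param slope_db Inverse steepness in dB (> 0).
#' @param guess_rate Chance level (default 1/3 for 3IFC).
#' @param lapse_rate Lapse probability in `[0, 0.1]` (default 0).
#' @param seed Seed making single-trial responses reproducible.
#' @return A `sim_listener` object.
#' @export
sim_listener <- function(true_threshold_db, slope_db = 1, guess_rate = 1 / 3,
                         lapse_rate = 0, seed = 1L) {
  if (any(slope_db <= 0)) stop("`slope_db` must be > 0", call. = FALSE)
  if (guess_rate < 0 || guess_rate >= 1) stop("`guess_rate` must be in [0, 1)", call. = FALSE)
  if (lapse_rate < 0 || lapse_rate > 0.1) stop("`lapse_rate` must be in [0, 0.1]", call. = FALSE)
  structure(list(true_threshold_db = true_threshold_db, slope_db = slope_db,
                 guess_rate = guess_rate, lapse_rate = lapse_rate,
                 seed = as.integer(seed)),
            class = "sim_listener")
}

listener_threshold_at <- function(listener, freq_hz = NULL) {
  th <- listener$true_threshold_db
  if (length(th) == 1L && is.null(names(th))) return(unname(th))
  if (is.null(freq_hz)) return(unname(th[1]))
  key <- as.character(freq_hz)
  if (!key %in% names(th)) {
    stop(sprintf("listener has no threshold for %s Hz", key), call. = FALSE)
  }
  unname(th[key])
}

# Psychometric probability of a correct (or detected) response.
p_correct <- function(listener, level_db, freq_hz = NULL, guess = NULL) {
  th <- listener_threshold_at(listener, freq_hz)
  g <- if (is.null(guess)) listener$guess_rate else guess
  g + (1 - g - listener$lapse_rate) *
    stats::plogis((level_db - th) / listener$slope_db)
}

#' Simulate one forced-choice response
#'
#' Correct with probability `p(L)` (see [sim_listener()]); deterministic in
#' `(listener$seed, trial_index)`.
#'
#' @param listener A `sim_listener`.
#' @param stimulus_level_db Probe level in dB re 1 V RMS.
#' @param trial_index Integer trial counter.
#' @return Logical: was the response correct?
#' @export
simulate_response <- function(listener, stimulus_level_db, trial_index) {
  stopifnot(inherits(listener, "sim_listener"))
  u <- with_seed(derive_seed(listener$seed, trial_index), stats::runif(1))
  u < p_correct(listener, stimulus_level_db)
}

#' Start a fresh staircase track
#'
#' @param config A [staircase_config()].
#' @return An unfinished `staircase_track` positioned at the initial level.
#' @export
staircase_track <- function(config = staircase_config()) {
  structure(list(level_db = config$initial_level_db,
                 step_db = config$step_large_db,
                 n_consecutive_correct = 0L,
                 direction = 0L,
                 trials = tibble::tibble(trial = integer(),
                                         level_db = numeric(),
                                         correct = logical(),
                                         is_reversal = logical()),
                 reversal_levels = numeric(),
                 threshold_db = NA_real_,
                 finished = FALSE),
            class = "staircase_track")
}

#' Advance a staircase by one response
#'
#' Applies the transformed up-down bookkeeping: the level steps down after
#' `down_rule` consecutive correct responses and up after any incorrect one;
#' the consecutive-correct counter resets on every level change and on every
#' incorrect response. A reversal is logged (at the level of the current
#' trial) whenever the movement direction flips; the step size drops from 4 to
#' 2 dB starting with the first level change after reversal
#' `reversals_to_small_step`, and the track finishes at `total_reversals`
#' with `threshold_db` set to the mean of the last `reversals_averaged`
#' reversal levels.
#'
#' @param track A `staircase_track` (not finished).
#' @param correct Logical response for the trial presented at
#'   `track$level_db`.
#' @param config The [staircase_config()] governing the track.
#' @return The updated `staircase_track`.
#' @export
staircase_update <- function(track, correct, config = staircase_config()) {
  stopifnot(inherits(track, "staircase_track"))
  if (track$finished) stop("track is already finished", call. = FALSE)
  level <- track$level_db

  move <- 0
  if (isTRUE(correct)) {
    track$n_consecutive_correct <- track$n_consecutive_correct + 1L
    if (track$n_consecutive_correct >= config$down_rule) {
      move <- -track$step_db
      track$n_consecutive_correct <- 0L
    }
  } else {
    move <- +track$step_db
    track$n_consecutive_correct <- 0L
  }

  is_reversal <- FALSE
  if (move != 0) {
    if (track$direction != 0L && sign(move) != track$direction) {
      is_reversal <- TRUE
      track$reversal_levels <- c(track$reversal_levels, level)
      n_rev <- length(track$reversal_levels)
      if (n_rev >= config$reversals_to_small_step) {
        track$step_db <- config$step_small_db
      }
      if (n_rev >= config$total_reversals) {
        track$finished <- TRUE
        tail_levels <- utils::tail(track$reversal_levels,
                                   config$reversals_averaged)
        track$threshold_db <- mean(tail_levels)
      }
    }
    track$direction <- as.integer(sign(move))
    track$level_db <- level + move
  }

  track$trials <- tibble::add_row(track$trials,
                                  trial = nrow(track$trials) + 1L,
                                  level_db = level,
                                  correct = isTRUE(correct),
                                  is_reversal = is_reversal)
  track
}

#' @export
print.staircase_track <- function(x, ...) {
  state <- if (x$finished) sprintf("finished, threshold %.2f dB", x$threshold_db)
    else sprintf("running at %.1f dB", x$level_db)
  cat(sprintf("<staircase_track: %d trials, %d reversals, %s>\n",
              nrow(x$trials), length(x$reversal_levels), state))
  invisible(x)
}

#' Run a complete adaptive staircase against a simulated listener
#'
#' @param listener A [sim_listener()].
#' @param config A [staircase_config()].
#' @param seed Seed for the response randomness; identical
#'   `(listener, config, seed)` give identical tracks.
#' @param freq_hz Optional frequency key when the listener holds per-frequency
#'   thresholds.
#' @param max_trials Safety cap (default 500); exceeding it raises a
#'   `ctcsim_nonconvergence` error carrying the partial track in its `track`
#'   field.
#' @return A finished `staircase_track`.
#' @export
run_staircase <- function(listener, config = staircase_config(), seed = 1L,
                          freq_hz = NULL, max_trials = 500L) {
  stopifnot(inherits(listener, "sim_listener"),
            inherits(config, "staircase_config"))
  draws <- with_seed(seed, stats::runif(max_trials))
  track <- staircase_track(config)
  for (i in seq_len(max_trials)) {
    p <- p_correct(listener, track$level_db, freq_hz)
    track <- staircase_update(track, draws[i] < p, config)
    if (track$finished) return(track)
  }
  stop(structure(class = c("ctcsim_nonconvergence", "error", "condition"),
                 list(message = sprintf("staircase did not finish within %d trials",
                                        max_trials),
                      call = sys.call(-1), track = track)))
}

#' Target percent-correct level of a transformed up-down rule
#'
#' Computes, by root finding on the listener's psychometric function, the
#' level the staircase converges to: for a 2-down/1-up rule the equilibrium
#' satisfies `p(L)^2 = 1/2`, i.e. p = 0.7071.
#'
#' @param listener A [sim_listener()].
#' @param down_rule Down rule (default 2).
#' @param freq_hz Optional frequency key.
#' @return Level in dB at which `p(correct) = (1/2)^(1/down_rule)`.
#' @export
staircase_target_level <- function(listener, down_rule = 2L, freq_hz = NULL) {
  p_target <- 0.5^(1 / down_rule)
  th <- listener_threshold_at(listener, freq_hz)
  f <- function(L) p_correct(listener, L, freq_hz) - p_target
  span <- max(20, 50 * listener$slope_db)
  stats::uniroot(f, c(th - span, th + span), tol = 1e-10)$root
}

#' Bracketing-audiometry settings
#'
#' The manual audiometric bracketing rule: start clearly audible, descend in
#' 10 dB steps until the tone is missed, ascend in 5 dB steps until heard,
#' repeat; threshold is the lowest level detected in at least 2 of 3
#' presentations.
#'
#' @param start_level_db Starting level (default 30 dB re the nominal scale).
#' @param down_step_db Descending step (default 10).
#' @param up_step_db Ascending step (default 5).
#' @param detections_required Detections needed at threshold (default 2).
#' @param presentations Presentations per level counted toward the rule
#'   (default 3).
#' @return A `bracketing_config` object.
#' @export
bracketing_config <- function(start_level_db = 30, down_step_db = 10,
                              up_step_db = 5, detections_required = 2L,
                              presentations = 3L) {
  if (down_step_db <= 0 || up_step_db <= 0) stop("steps must be > 0", call. = FALSE)
  structure(list(start_level_db = start_level_db, down_step_db = down_step_db,
                 up_step_db = up_step_db,
                 detections_required = as.integer(detections_required),
                 presentations = as.integer(presentations)),
            class = "bracketing_config")
}

# Detection probability for a yes/no audiometric presentation: no guessing
# term (unlike the forced-choice task).
p_detect <- function(listener, level_db, freq_hz) {
  p_correct(listener, level_db, freq_hz, guess = 0)
}

#' Bracketing audiometry against a simulated listener
#'
#' Runs the descending/ascending bracketing procedure per frequency,
#' presenting frequencies in the audiometric order (1000 Hz first, then the
#' remaining frequencies ascending). All probed levels stay on the 5 dB grid
#' anchored at `start_level_db`.
#'
#' @param listener A [sim_listener()] (scalar or per-frequency thresholds).
#' @param config A [bracketing_config()].
#' @param freqs_hz Frequencies to test (default the audiometric set
#'   `c(250, 500, 1000, 2000, 4000)`).
#' @param seed Seed for response randomness.
#' @param max_presentations Per-frequency cap (default 200); exceeding it
#'   raises a `ctcsim_nonconvergence` error.
#' @return Named numeric vector: threshold in dB per frequency, ordered as
#'   tested.
#' @export
run_bracketing <- function(listener, config = bracketing_config(),
                           freqs_hz = c(250, 500, 1000, 2000, 4000),
                           seed = 1L, max_presentations = 200L) {
  stopifnot(inherits(listener, "sim_listener"),
            inherits(config, "bracketing_config"))
  order_hz <- if (1000 %in% freqs_hz) {
    c(1000, sort(freqs_hz[freqs_hz != 1000]))
  } else sort(freqs_hz)
  out <- numeric(0)
  for (fi in seq_along(order_hz)) {
    f <- order_hz[fi]
    draws <- with_seed(derive_seed(seed, fi), stats::runif(max_presentations))
    k <- 0L
    present <- function(level) {
      k <<- k + 1L
      draws[k] < p_detect(listener, level, f)
    }
    detections <- new.env(parent = emptyenv())  # level -> detection count
    tally <- function(level, heard) {
      key <- sprintf("%.1f", level)
      n <- if (is.null(detections[[key]])) 0L else detections[[key]]
      detections[[key]] <- n + as.integer(heard)
    }
    qualifying <- function() {
      keys <- ls(detections)
      lv <- as.numeric(keys)
      det <- vapply(keys, function(kk) detections[[kk]], integer(1))
      lv[det >= config$detections_required]
    }
    level <- config$start_level_db
    # initial descent: drop until the first miss (a ceaselessly detecting
    # listener bottoms out at the lowest level the budget allows)
    descended <- FALSE
    while (k < max_presentations) {
      heard <- present(level)
      tally(level, heard)
      if (!heard) { descended <- TRUE; break }
      level <- level - config$down_step_db
    }
    if (!descended) {
      out[as.character(f)] <- level + config$down_step_db
      next
    }
    threshold <- NA_real_
    while (k < max_presentations) {
      # ascend until heard
      heard <- FALSE
      while (!heard && k < max_presentations) {
        level <- level + config$up_step_db
        heard <- present(level)
        tally(level, heard)
      }
      ok <- qualifying()
      if (length(ok) > 0L) { threshold <- min(ok); break }
      level <- level - config$down_step_db
    }
    if (is.na(threshold)) {
      stop(structure(class = c("ctcsim_nonconvergence", "error", "condition"),
                     list(message = sprintf("bracketing at %g Hz did not settle within %d presentations",
                                            f, max_presentations),
                          call = NULL)))
    }
    out[as.character(f)] <- threshold
  }
  out
}

#' Threshold improvement from crosstalk cancellation
#'
#' @param without_db Threshold without cancellation (dB re 1 V RMS).
#' @param with_db Threshold with cancellation.
#' @return `without_db - with_db`; positive values mean cancellation lowered
#'   (improved) the masked threshold.
#' @export
threshold_improvement <- function(without_db, with_db) {
  if (!all(is.finite(c(without_db, with_db)))) {
    stop("thresholds must be finite", call. = FALSE)
  }
  without_db - with_db
}

#' Occlusion effect from paired audiograms
#'
#' @param occluded_thresholds,unoccluded_thresholds Named numeric vectors of
#'   bone-conduction thresholds (dB) keyed by frequency; keys must match.
#' @return Named vector `unoccluded - occluded` per frequency; positive values
#'   mean occlusion lowered the BC threshold (the conventional sign).
#' @export
occlusion_effect <- function(occluded_thresholds, unoccluded_thresholds) {
  ko <- names(occluded_thresholds); ku <- names(unoccluded_thresholds)
  if (is.null(ko) || is.null(ku) || !setequal(ko, ku) ||
      length(ko) != length(ku)) {
    stop("occluded and unoccluded thresholds must share the same frequency keys",
         call. = FALSE)
  }
  unoccluded_thresholds[ko] - occluded_thresholds
}
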