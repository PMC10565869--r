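#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a staircase track into its trial log
#'
#' @param x A `staircase_track`.
#' @param ... Unused.
#' @return Tibble with `trial`, `level_db`, `correct`, `is_reversal`.
#' @export
tidy.staircase_track <- function(x, ...) x$trials

#' One-row summary of a staircase track
#'
#' @param x A `staircase_track`.
#' @param ... Unused.
#' @return Tibble with `threshold_db`, `n_trials`, `n_reversals`, `finished`.
#' @export
glance.staircase_track <- function(x, ...) {
  tibble::tibble(threshold_db = x$threshold_db,
                 n_trials = nrow(x$trials),
                 n_reversals = length(x$reversal_levels),
                 finished = x$finished)
}

#' Tidy a reduction report into its per-band table
#'
#' @param x A `reduction_report`.
#' @param ... Unused.
#' @return Tibble with `center_hz`, `reduction_db`.
#' @export
tidy.reduction_report <- function(x, ...) x$per_third_octave

#' One-row summary of a reduction report
#'
#' @param x A `reduction_report`.
#' @param ... Unused.
#' @return Tibble with the in-band levels and reduction.
#' @export
glance.reduction_report <- function(x, ...) {
  tibble::tibble(level_without_db = x$level_without_db,
                 level_with_db = x$level_with_db,
                 reduction_db = x$reduction_db,
                 broadband_reduction_db = x$broadband_reduction_db,
                 f_lo_hz = x$band[1], f_hi_hz = x$band[2])
}

#' Tidy an FxLMS trace
#'
#' @param x An `fxlms_trace`.
#' @param ... Unused.
#' @return Tibble with `time_s` and `error` per sample.
#' @export
tidy.fxlms_trace <- function(x, ...) {
  tibble::tibble(time_s = (seq_along(x$error_history) - 1L) / x$rate_hz,
                 error = x$error_history)
}

#' One-row summary of an FxLMS trace
#'
#' @param x An `fxlms_trace`.
#' @param ... Unused.
#' @return Tibble with convergence time and first/last-quarter error power.
#' @export
glance.fxlms_trace <- function(x, ...) {
  e <- x$error_history
  q <- max(1L, length(e) %/% 4L)
  tibble::tibble(converged_at_s = x$converged_at_s,
                 n_blocks = length(x$coefficient_change),
                 initial_error_power = mean(e[seq_len(q)]^2),
                 final_error_power = mean(e[(length(e) - q + 1L):length(e)]^2))
}

#' Plot a staircase track
#'
#' Level against trial number with reversals marked and the final threshold
#' shown as a dashed line.
#'
#' @param object A `staircase_track`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.staircase_track <- function(object, ...) {
  df <- object$trials
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$level_db)) +
    ggplot2::geom_step(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$correct)) +
    ggplot2::geom_point(data = df[df$is_reversal, , drop = FALSE],
                        colour = "red", size = 3, shape = 1) +
    ggplot2::labs(x = "Trial", y = "Probe level (dB re 1 V RMS)",
                  shape = "Correct") +
    ggplot2::theme_minimal()
  if (object$finished) {
    p <- p + ggplot2::geom_hline(yintercept = object$threshold_db,
                                 linetype = "dashed")
  }
  p
}

#' Plot FxLMS error convergence
#'
#' @param object An `fxlms_trace`.
#' @param downsample Keep every k-th sample for plotting (default keeps about
#'   5000 points).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fxlms_trace <- function(object, downsample = NULL, ...) {
  df <- tidy.fxlms_trace(object)
  if (is.null(downsample)) downsample <- max(1L, nrow(df) %/% 5000L)
  df <- df[seq(1L, nrow(df), by = downsample), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$error)) +
    ggplot2::geom_line(colour = "darkgreen", linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Error signal e(n)") +
    ggplot2::theme_minimal()
}

#' Plot per-band crosstalk reduction
#'
#' @param object A `reduction_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reduction_report <- function(object, ...) {
  df <- object$per_third_octave
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$center_hz),
                                   y = .data$reduction_db)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$reduction_db,
                        linetype = "dashed") +
    ggplot2::labs(x = "Third-octave center (Hz)",
                  y = "Crosstalk reduction (dB)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
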