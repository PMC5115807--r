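#' Subtract the pre-light baseline from a photocurrent trace
#'
#' The mean current over a window preceding light onset is subtracted from
#' the whole current vector, so that the dark current defines zero. All
#' metadata are preserved.
#'
#' @param trace A [photocurrent_trace()].
#' @param baseline_window `c(from, to)` in seconds, lying before `light_on`.
#'   Defaults to everything from the start of the record to light onset.
#' @return The baseline-subtracted `photocurrent_trace`.
#' @export
baseline_subtract <- function(trace, baseline_window = NULL) {
  if (is.null(baseline_window))
    baseline_window <- c(trace$time[1], trace$light_on)
  check_epoch(baseline_window, "baseline_window",
              t_min = trace$time[1], t_max = trace$time[length(trace$time)])
  if (baseline_window[2] > trace$light_on)
    stop_range("baseline_window must end at or before light_on")
  idx <- epoch_idx(trace$time, baseline_window[1], baseline_window[2])
  if (length(idx) == 0) stop_range("baseline_window contains no samples")
  trace$current <- trace$current - mean(trace$current[idx])
  trace
}

#' Extract peak and steady-state photocurrent features
#'
#' Computes the standard descriptors of a pump photocurrent from a
#' baseline-subtracted trace:
#' \itemize{
#'   \item `i_p` — peak current density (pA/pF): the maximum in-light
#'     current divided by the whole-cell capacitance. The peak is located on
#'     a 1-kHz low-pass (1-ms boxcar) copy of the trace so that a single
#'     noise sample cannot set it, matching the analogue filter bandwidth
#'     of typical patch-clamp hardware.
#'   \item `i_ss` — steady-state current density (pA/pF): the mean current
#'     over the final `steady_window` seconds before light offset, divided
#'     by capacitance. Small negative values arising from noise are clamped
#'     to 0 with a warning.
#'   \item `inactivation_ratio` — `(i_p - i_ss) / i_p`, the fractional
#'     decay from peak to steady state (0 when `i_p` is 0).
#' }
#'
#' @param trace A baseline-subtracted [photocurrent_trace()].
#' @param steady_window Length of the terminal averaging window (s).
#' @return A list of class `trace_features` with fields `i_p`, `i_ss`,
#'   `inactivation_ratio`, plus the trace's `irradiance` and
#'   `holding_potential` for downstream grouping.
#' @export
extract_features <- function(trace, steady_window = 0.05) {
  check_scalar(steady_window, "steady_window", positive = TRUE)
  if (trace$light_off - trace$light_on < steady_window)
    stop_range("light epoch shorter than steady_window")
  fs <- sample_rate(trace)
  lit <- epoch_idx(trace$time, trace$light_on, trace$light_off)
  if (length(lit) == 0) stop_range("light epoch contains no samples")

  w <- max(1L, round(fs / 1000))          # 1-ms boxcar ~ 1-kHz low-pass
  smoothed <- if (w > 1) {
    as.numeric(stats::filter(trace$current, rep(1 / w, w), sides = 2))
  } else trace$current
  sm_lit <- smoothed[lit]
  sm_lit[is.na(sm_lit)] <- trace$current[lit][is.na(sm_lit)]
  i_p <- max(sm_lit) / trace$capacitance

  ss_idx <- epoch_idx(trace$time, trace$light_off - steady_window,
                      trace$light_off)
  i_ss <- mean(trace$current[ss_idx]) / trace$capacitance
  if (i_ss < 0) {
    warning("negative steady-state current clamped to 0")
    i_ss <- 0
  }
  ratio <- if (i_p > 0) (i_p - i_ss) / i_p else 0
  ratio <- min(max(ratio, 0), 1)
  structure(list(i_p = i_p, i_ss = i_ss, inactivation_ratio = ratio,
                 irradiance = trace$irradiance,
                 holding_potential = trace$holding_potential),
            class = "trace_features")
}

#' @export
print.trace_features <- function(x, ...) {
  cat(sprintf(
    "<trace_features> i_p = %.3f pA/pF, i_ss = %.3f pA/pF, ratio = %.3f\n",
    x$i_p, x$i_ss, x$inactivation_ratio))
  invisible(x)
}
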