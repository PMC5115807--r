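# internal argument checks -------------------------------------------------

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("narpump_param_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("narpump_data_error", "error")))
}

stop_range <- function(...) {
  stop(errorCondition(paste0(...), class = c("narpump_range_error", "error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("narpump_degenerate_error", "error")))
}

stop_fit <- function(...) {
  stop(errorCondition(paste0(...), class = c("narpump_fit_error", "error")))
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(name, " must be a finite numeric scalar")
  if (positive && x <= 0) stop_param(name, " must be > 0")
  if (nonneg && x < 0) stop_param(name, " must be >= 0")
  invisible(x)
}

check_epoch <- function(epoch, name, t_min = NULL, t_max = NULL) {
  if (!is.numeric(epoch) || length(epoch) != 2L || any(!is.finite(epoch)) ||
      epoch[1] >= epoch[2])
    stop_param(name, " must be c(start, end) with start < end")
  if (!is.null(t_min) && epoch[1] < t_min)
    stop_range(name, " starts before the record")
  if (!is.null(t_max) && epoch[2] > t_max)
    stop_range(name, " ends after the record")
  invisible(epoch)
}

# index range of samples inside [from, to)
epoch_idx <- function(time, from, to) {
  which(time >= from & time < to)
}
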