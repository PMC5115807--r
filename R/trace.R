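#' Construct a photocurrent trace
#'
#' Bundles a sampled whole-cell current recording with the metadata the
#' downstream analyses need: membrane capacitance, the light epoch,
#' irradiance, wavelength band and holding potential. Outward (pump) current
#' is positive by convention.
#'
#' @param time Numeric vector of sample times (s), a strictly increasing
#'   uniform grid.
#' @param current Numeric vector of currents (pA), same length as `time`.
#' @param capacitance Whole-cell capacitance (pF), > 0.
#' @param light_on,light_off Light epoch boundaries (s), within the record.
#' @param irradiance Stimulus irradiance (mW/mm^2), or `NA`.
#' @param wavelength_band Wavelength band (nm), or `NA`.
#' @param holding_potential Holding potential (mV), or `NA`.
#'
#' @return An object of class `photocurrent_trace`.
#' @export
photocurrent_trace <- function(time, current, capacitance,
                               light_on, light_off,
                               irradiance = NA_real_,
                               wavelength_band = NA_real_,
                               holding_potential = NA_real_) {
  if (length(time) != length(current))
    stop_param("time and current must have equal length")
  if (length(time) < 2L) stop_param("trace needs at least two samples")
  dt <- diff(time)
  if (any(dt <= 0)) stop_param("time grid must be strictly increasing")
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop_param("time grid must be uniform")
  check_scalar(capacitance, "capacitance", positive = TRUE)
  check_epoch(c(light_on, light_off), "light epoch",
              t_min = time[1], t_max = time[length(time)])
  structure(
    list(time = as.numeric(time), current = as.numeric(current),
         capacitance = capacitance,
         light_on = light_on, light_off = light_off,
         irradiance = irradiance, wavelength_band = wavelength_band,
         holding_potential = holding_potential),
    class = "photocurrent_trace")
}

#' @export
print.photocurrent_trace <- function(x, ...) {
  cat("<photocurrent_trace>\n")
  cat(sprintf("  %d samples at %.0f Hz, %.3f-%.3f s\n",
              length(x$time), 1 / mean(diff(x$time)),
              x$time[1], x$time[length(x$time)]))
  cat(sprintf("  light %.3f-%.3f s, capacitance %.1f pF\n",
              x$light_on, x$light_off, x$capacitance))
  if (is.finite(x$irradiance))
    cat(sprintf("  irradiance %.2f mW/mm^2\n", x$irradiance))
  invisible(x)
}

sample_rate <- function(trace) 1 / mean(diff(trace$time))

#' Read and write photocurrent traces as delimited text
#'
#' Traces travel as two-column (time, current) tab-separated text with the
#' recording metadata in `# key: value` header lines, so that a trace file
#' is self-contained and diffable.
#'
#' @param trace A [photocurrent_trace()].
#' @param path File path.
#' @return `read_trace` returns a `photocurrent_trace`; `write_trace`
#'   returns `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  meta <- c(capacitance = trace$capacitance, light_on = trace$light_on,
            light_off = trace$light_off, irradiance = trace$irradiance,
            wavelength_band = trace$wavelength_band,
            holding_potential = trace$holding_potential)
  hdr <- sprintf("# %s: %.10g", names(meta), meta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(data.frame(time = trace$time, current = trace$current),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- strsplit(sub("^#\\s*", "", ln), ":\\s*")[[1]]
    meta[[kv[1]]] <- as.numeric(kv[2])
  }
  tab <- utils::read.table(text = lines[!is_meta], header = TRUE, sep = "\t")
  photocurrent_trace(tab$time, tab$current,
                     capacitance = meta$capacitance,
                     light_on = meta$light_on, light_off = meta$light_off,
                     irradiance = meta$irradiance %||% NA_real_,
                     wavelength_band = meta$wavelength_band %||% NA_real_,
                     holding_potential = meta$holding_potential %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
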