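#' Construct a current-voltage series
#'
#' One current value per holding potential. The series must include 0 mV,
#' the anchor used for normalization.
#'
#' @param voltage Holding potentials (mV), unique, including 0.
#' @param current Currents (pA/pF, or normalized units when
#'   `normalized = TRUE`).
#' @param normalized Logical: are the currents already expressed relative
#'   to the 0-mV value?
#' @return An object of class `iv_series`.
#' @export
iv_series <- function(voltage, current, normalized = FALSE) {
  if (length(voltage) != length(current))
    stop_param("voltage and current must have equal length")
  if (anyDuplicated(voltage)) stop_param("one entry per voltage required")
  if (!any(voltage == 0)) stop_param("series must include 0 mV")
  structure(list(voltage = as.numeric(voltage),
                 current = as.numeric(current),
                 normalized = isTRUE(normalized)),
            class = "iv_series")
}

#' Normalize an I-V series to its 0-mV current
#'
#' Every current is divided by the current at 0 mV holding potential, so the
#' series expresses voltage dependence as a relative value with the 0-mV
#' entry exactly 1. Idempotent: normalizing twice changes nothing.
#'
#' @param series An [iv_series()].
#' @return The normalized `iv_series`.
#' @export
normalize_iv <- function(series) {
  i0 <- series$current[series$voltage == 0]
  if (i0 == 0)
    stop_degenerate("current at 0 mV is zero; cannot normalize")
  series$current <- series$current / i0
  series$normalized <- TRUE
  series
}

#' Estimate the negative-region slope S_neg of a normalized I-V series
#'
#' Ordinary least-squares line through the points at non-positive holding
#' potentials. The slope quantifies how strongly the pump current falls at
#' hyperpolarized potentials and is reported in the conventional
#' 10^-3 mV^-1 units, so a normalized current dropping from 1 at 0 mV to
#' 0.4 at -80 mV gives a slope of 7.5.
#'
#' @param series A normalized [iv_series()].
#' @param include_zero Logical: include the 0-mV anchor point in the
#'   regression (default) or restrict to strictly negative potentials.
#' @return A list of class `sneg_estimate`: `slope` (10^-3 mV^-1),
#'   `intercept` (unitless), `n_points`.
#' @export
estimate_sneg <- function(series, include_zero = TRUE) {
  if (!isTRUE(series$normalized))
    stop_data("series must be normalized (see normalize_iv)")
  keep <- if (include_zero) series$voltage <= 0 else series$voltage < 0
  if (sum(keep) < 3)
    stop_data("need >= 3 points in the negative voltage region")
  fit <- stats::lm(current ~ voltage,
                   data = data.frame(voltage = series$voltage[keep],
                                     current = series$current[keep]))
  cf <- stats::coef(fit)
  structure(list(slope = unname(cf["voltage"]) * 1e3,
                 intercept = unname(cf["(Intercept)"]),
                 n_points = sum(keep)),
            class = "sneg_estimate")
}

#' @export
print.sneg_estimate <- function(x, ...) {
  cat(sprintf("<sneg_estimate> S_neg = %.3f x 10^-3 mV^-1 (n = %d)\n",
              x$slope, x$n_points))
  invisible(x)
}

#' Compute irradiance-corrected relative action spectra
#'
#' For each cell, the steady-state photocurrent at each wavelength is
#' divided by the irradiance delivered at that wavelength (power-density
#' correction), normalized to the cell's maximum, and then averaged across
#' cells wavelength by wavelength. The power-density correction follows the
#' standard convention for these measurements; set
#' `photon_flux = TRUE` to divide instead by photon flux
#' (irradiance x wavelength), which weights by photons rather than power.
#'
#' @param measurements A data.frame with columns `wavelength` (nm),
#'   `irradiance` (mW/mm^2, > 0), `i_ss` (pA/pF) and `cell_id`.
#' @param photon_flux Logical: correct by photon flux instead of power
#'   density.
#' @return A list of class `relative_spectrum`: `per_cell` (data.frame of
#'   normalized sensitivities), `average` (data.frame with `wavelength`,
#'   `mean_sensitivity`, `sem`, `n`), and `peak_wavelength` (argmax of the
#'   averaged spectrum, nm).
#' @export
action_spectrum <- function(measurements, photon_flux = FALSE) {
  req <- c("wavelength", "irradiance", "i_ss", "cell_id")
  if (!is.data.frame(measurements) || !all(req %in% names(measurements)))
    stop_param("measurements needs columns ", paste(req, collapse = ", "))
  if (any(measurements$irradiance <= 0))
    stop_param("irradiances must be > 0")
  per_cell <- do.call(rbind, lapply(split(measurements,
                                          measurements$cell_id),
    function(d) {
      if (anyDuplicated(d$wavelength))
        stop_data("duplicate wavelength within cell ", d$cell_id[1])
      denom <- if (photon_flux) d$irradiance * d$wavelength else d$irradiance
      s <- d$i_ss / denom
      data.frame(cell_id = d$cell_id, wavelength = d$wavelength,
                 relative_sensitivity = s / max(s))
    }))
  rownames(per_cell) <- NULL
  avg <- do.call(rbind, lapply(split(per_cell, per_cell$wavelength),
    function(d) data.frame(
      wavelength = d$wavelength[1],
      mean_sensitivity = mean(d$relative_sensitivity),
      sem = if (nrow(d) > 1)
        stats::sd(d$relative_sensitivity) / sqrt(nrow(d)) else NA_real_,
      n = nrow(d))))
  avg <- avg[order(avg$wavelength), ]
  rownames(avg) <- NULL
  structure(list(per_cell = per_cell, average = avg,
                 peak_wavelength = avg$wavelength[
                   which.max(avg$mean_sensitivity)]),
            class = "relative_spectrum")
}
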