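# Irradiance-response fitting. The photocurrent of a single-photon
# rhodopsin photocycle saturates with irradiance as a Michaelis-Menten
# hyperbola y = Imax*x/(x+KD); some pumps additionally show a power-dependent
# current suppression above a threshold irradiance, modelled by subtracting
# a second hyperbola in (x - T). Fits use Levenberg-Marquardt least squares
# (minpack.lm) with bounds and multi-start initialization.

as_dose_response <- function(data) {
  if (inherits(data, "dose_response")) return(data)
  if (is.data.frame(data) &&
      all(c("irradiance", "response") %in% names(data)))
    return(dose_response(data$irradiance, data$response,
                         cell_id = if ("cell_id" %in% names(data))
                           data$cell_id[1] else "cell1"))
  stop_param("data must be a dose_response or a data.frame with ",
             "irradiance and response columns")
}

mm_bounds <- function(y) {
  list(lower = c(imax = 0, kd = 1e-3),
       upper = c(imax = 10 * max(abs(y)), kd = 1e4))
}

# try Levenberg-Marquardt and the port trust-region optimizer from every
# start; keep the converged fit with the smallest residual sum of squares
run_nls_starts <- function(formula, data, starts, lower, upper) {
  fits <- list()
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
    g <- tryCatch(
      stats::nls(formula, data = data, start = st, algorithm = "port",
                 lower = lower, upper = upper,
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = FALSE)),
      error = function(e) NULL)
    if (!is.null(g)) fits[[length(fits) + 1L]] <- g
  }
  if (length(fits) == 0)
    stop_fit("nonlinear fit failed for every start; ",
             "n = ", nrow(data), ", response range [",
             paste(signif(range(data$y), 4), collapse = ", "), "]")
  sse <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
  fits[[which.min(sse)]]
}

#' Fit the Michaelis-Menten irradiance-response model
#'
#' Least-squares fit of `y = imax * x / (x + kd)` to irradiance-response
#' points, giving the saturating amplitude `imax` and the half-saturation
#' irradiance `kd` (the apparent K_D of the photocurrent). Initialization is
#' multi-start (`kd` started at the irradiance nearest half-maximal response
#' and at the median irradiance) with physical bounds, so convergence does
#' not depend on a lucky guess.
#'
#' @param data A [dose_response()] or a data.frame with `irradiance` and
#'   `response` columns.
#' @return A list of class `mm_fit`: `imax` (pA/pF), `kd` (mW/mm^2),
#'   `residual_sse`, `n`, `boundary` (`TRUE` when `kd` ran to its lower
#'   bound, i.e. the data are saturated and `kd` is not identified), and
#'   `cell_id`.
#' @export
fit_mm <- function(data) {
  d <- as_dose_response(data)
  x <- d$irradiance; y <- d$response
  if (length(unique(x)) < 3)
    stop_data("fit_mm needs >= 3 distinct irradiances")
  b <- mm_bounds(y)
  imax0 <- max(y)
  half <- x[which.min(abs(y - imax0 / 2))]
  starts <- list(list(imax = imax0, kd = max(half, 1e-2)),
                 list(imax = imax0, kd = stats::median(x)))
  df <- data.frame(x = x, y = y)
  fit <- run_nls_starts(y ~ imax * x / (x + kd), df, starts,
                        b$lower, b$upper)
  cf <- stats::coef(fit)
  structure(list(imax = unname(cf["imax"]), kd = unname(cf["kd"]),
                 residual_sse = sum(stats::resid(fit)^2),
                 n = length(x),
                 boundary = cf["kd"] <= 1.5 * b$lower["kd"],
                 cell_id = d$cell_id),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> imax = %.4g pA/pF, KD = %.4g mW/mm^2 (n = %d%s)\n",
              x$imax, x$kd, x$n,
              if (isTRUE(x$boundary)) ", boundary fit" else ""))
  invisible(x)
}

#' Fit the suppression-subtracted composite irradiance-response model
#'
#' Fits `y = imax*x/(x+kd1) - supp_amp*(x-T)/((x-T)+kd2)` for `x > T`
#' (plain hyperbola below the threshold `T`, which is fixed, not fitted).
#' This composite describes pumps whose steady-state photocurrent is
#' suppressed at high irradiance: the response rises along a hyperbola and
#' then bends down above the threshold.
#'
#' @param data A [dose_response()] or equivalent data.frame.
#' @param threshold Suppression threshold T (mW/mm^2), held fixed.
#' @return A list of class `suppressed_mm_fit`: `imax`, `kd1`, `supp_amp`,
#'   `threshold`, `kd2`, `residual_sse`, `n`, and `negative_values`
#'   (`TRUE` when the fitted model dips below zero inside the observed
#'   irradiance range — a fit-quality flag, never silently clamped).
#' @export
fit_suppressed_mm <- function(data, threshold = 10) {
  d <- as_dose_response(data)
  x <- d$irradiance; y <- d$response
  check_scalar(threshold, "threshold", positive = TRUE)
  if (length(unique(x)) < 5)
    stop_data("fit_suppressed_mm needs >= 5 distinct irradiances")
  if (all(x <= threshold))
    stop_fit("all points at or below the threshold: ",
             "suppression component unidentifiable")
  if (!any(x <= threshold))
    stop_data("need points at or below the threshold to anchor the ",
              "plain hyperbola")

  # anchor starts on the sub-threshold branch where the model is a plain MM
  base <- tryCatch({
    keep <- x <= threshold
    if (sum(keep) >= 3) fit_mm(dose_response(x[keep], y[keep])) else
      fit_mm(d)
  }, error = function(e) fit_mm(d))
  xs <- x[x > threshold]
  supp0 <- max(mm_response(max(x), base$imax, base$kd) - y[which.max(x)],
               0.05 * base$imax)
  b <- mm_bounds(y)
  lower <- c(imax = 0, kd1 = 1e-3, supp_amp = 0, kd2 = 1e-3)
  upper <- c(imax = unname(b$upper["imax"]), kd1 = 1e4,
             supp_amp = unname(b$upper["imax"]), kd2 = 1e4)
  starts <- list(
    list(imax = base$imax, kd1 = base$kd, supp_amp = supp0,
         kd2 = stats::median(xs - threshold)),
    list(imax = base$imax, kd1 = base$kd, supp_amp = supp0,
         kd2 = 2 * threshold),
    list(imax = max(y), kd1 = stats::median(x), supp_amp = supp0,
         kd2 = stats::median(x)))
  df <- data.frame(x = x, y = y, xs = pmax(x - threshold, 0))
  fit <- run_nls_starts(
    y ~ imax * x / (x + kd1) - supp_amp * xs / (xs + kd2),
    df, starts, lower, upper)
  cf <- stats::coef(fit)
  grid <- seq(min(x), max(x), length.out = 512)
  pred <- suppressed_mm_response(grid, cf["imax"], cf["kd1"],
                                 cf["supp_amp"], threshold, cf["kd2"])
  structure(list(imax = unname(cf["imax"]), kd1 = unname(cf["kd1"]),
                 supp_amp = unname(cf["supp_amp"]), threshold = threshold,
                 kd2 = unname(cf["kd2"]),
                 residual_sse = sum(stats::resid(fit)^2),
                 n = length(x), negative_values = any(pred < 0),
                 cell_id = d$cell_id),
            class = "suppressed_mm_fit")
}

#' @export
print.suppressed_mm_fit <- function(x, ...) {
  cat(sprintf(
    "<suppressed_mm_fit> imax = %.4g, KD1 = %.4g, supp = %.4g, KD2 = %.4g (T = %.3g)\n",
    x$imax, x$kd1, x$supp_amp, x$kd2, x$threshold))
  if (isTRUE(x$negative_values))
    cat("  note: fitted model goes negative inside the data range\n")
  invisible(x)
}

#' Fit K_D on a restricted irradiance range
#'
#' Applies [fit_mm()] to the subset of points with irradiance at or below
#' `max_irradiance`. This is the conventional way to compare half-saturation
#' irradiances between pumps when one of them deviates from the plain
#' hyperbola at high power: the fit is restricted to the range where both
#' follow Michaelis-Menten behaviour.
#'
#' @param data A [dose_response()] or equivalent data.frame.
#' @param max_irradiance Upper irradiance cutoff (mW/mm^2); the default
#'   restricts to 0-12 mW/mm^2.
#' @return An `mm_fit` with an extra field `n_excluded`, the number of
#'   points dropped by the cutoff.
#' @export
fit_kd_restricted <- function(data, max_irradiance = 12) {
  d <- as_dose_response(data)
  check_scalar(max_irradiance, "max_irradiance", positive = TRUE)
  keep <- d$irradiance <= max_irradiance
  if (length(unique(d$irradiance[keep])) < 3)
    stop_data("fewer than 3 distinct irradiances at or below ",
              max_irradiance, " mW/mm^2")
  fit <- fit_mm(dose_response(d$irradiance[keep], d$response[keep],
                              cell_id = d$cell_id))
  fit$n_excluded <- sum(!keep)
  fit
}

#' Summarize per-cell fits as mean and SEM
#'
#' @param fits A list of `mm_fit` or `suppressed_mm_fit` objects.
#' @param field Parameter to summarize (e.g. `"kd"`, `"imax"`).
#' @return A list with `mean`, `sem` and `n`.
#' @export
summarize_fits <- function(fits, field = "kd") {
  vals <- vapply(fits, function(f) f[[field]], numeric(1))
  list(mean = mean(vals),
       sem = stats::sd(vals) / sqrt(length(vals)),
       n = length(vals))
}
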