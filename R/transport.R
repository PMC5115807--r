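#' Construct a pH-assay trace
#'
#' @param time Sample times (s).
#' @param ph pH values.
#' @param light_epoch Illumination epoch `c(on, off)` (s).
#' @param condition Ionic condition: `"NaCl"`, `"Na2SO4"`, or `"KCl"`.
#' @param cccp Logical: protonophore (CCCP) present?
#' @return An object of class `ph_trace`.
#' @export
ph_trace <- function(time, ph, light_epoch,
                     condition = c("NaCl", "Na2SO4", "KCl"), cccp = FALSE) {
  condition <- match.arg(condition)
  if (length(time) != length(ph))
    stop_param("time and ph must have equal length")
  check_epoch(light_epoch, "light_epoch",
              t_min = time[1], t_max = time[length(time)])
  structure(list(time = as.numeric(time), ph = as.numeric(ph),
                 light_epoch = light_epoch, condition = condition,
                 cccp = isTRUE(cccp)),
            class = "ph_trace")
}

#' Estimate the light-induced pH slope
#'
#' Fits a least-squares line to the central 80% of the illumination epoch
#' (avoiding onset/offset transients) and subtracts the pre-light baseline
#' slope, giving the light-induced pH drift in pH/min. The sign call uses a
#' dead band: drifts smaller than `dead_band` in magnitude are called 0.
#'
#' @param trace A [ph_trace()].
#' @param dead_band Magnitude (pH/min) below which the slope is called
#'   zero.
#' @return A list of class `ph_slope`: `slope` (pH/min, baseline-
#'   corrected), `sign` (-1, 0, +1), `light_slope`, `baseline_slope`,
#'   `condition`, `cccp`.
#' @export
ph_slope <- function(trace, dead_band = 0.005) {
  lit <- epoch_idx(trace$time, trace$light_epoch[1], trace$light_epoch[2])
  if (length(lit) < 30)
    stop_data("illumination epoch needs >= 30 samples")
  span <- trace$light_epoch[2] - trace$light_epoch[1]
  core <- epoch_idx(trace$time,
                    trace$light_epoch[1] + 0.1 * span,
                    trace$light_epoch[2] - 0.1 * span)
  slope_of <- function(idx) {
    if (length(idx) < 2) return(0)
    unname(stats::coef(stats::lm(trace$ph[idx] ~ trace$time[idx]))[2]) * 60
  }
  light_slope <- slope_of(core)
  base_idx <- which(trace$time < trace$light_epoch[1])
  baseline_slope <- slope_of(base_idx)
  slope <- light_slope - baseline_slope
  structure(list(slope = slope,
                 sign = if (abs(slope) < dead_band) 0L else
                   as.integer(sign(slope)),
                 light_slope = light_slope,
                 baseline_slope = baseline_slope,
                 condition = trace$condition, cccp = trace$cccp),
            class = "ph_slope")
}

#' Classify pump ion-transport activity from pH slopes
#'
#' Applies the suspension-assay decision logic. For an outward Na+ pump,
#' illumination alkalinizes NaCl (and Na2SO4) suspensions — the membrane
#' potential generated by electrogenic Na+ export drives secondary H+
#' uptake — and the protonophore CCCP enhances that uptake; in KCl, where
#' no transportable cation is present, the pump exports H+ instead, so pH
#' falls, and CCCP short-circuits the gradient, flattening the drift. The
#' mirror pattern in NaCl (acidification diminished by CCCP) indicates a
#' primary H+ pump. Anything else is inconclusive.
#'
#' "Enhanced"/"diminished" by CCCP means a relative slope-magnitude change
#' of at least `rel_change` with the sign retained (enhanced) or moved
#' toward zero (diminished).
#'
#' @param slopes A list of [ph_slope()] results covering NaCl with and
#'   without CCCP and KCl with and without CCCP; an Na2SO4 entry, if
#'   present, is used to check anion independence.
#' @param rel_change Minimum relative slope change treated as a CCCP
#'   effect.
#' @return A list of class `transport_call`: `verdict` (`"sodium_pump"`,
#'   `"proton_pump"` or `"inconclusive"`), `rationale`, `slopes`
#'   (data.frame of the inputs).
#' @export
classify_transport <- function(slopes, rel_change = 0.25) {
  tab <- do.call(rbind, lapply(slopes, function(s)
    data.frame(condition = s$condition, cccp = s$cccp, slope = s$slope,
               sign = s$sign)))
  pick <- function(cond, cccp) {
    row <- tab[tab$condition == cond & tab$cccp == cccp, ]
    if (nrow(row) == 0) NULL else row
  }
  nacl <- pick("NaCl", FALSE); nacl_c <- pick("NaCl", TRUE)
  kcl <- pick("KCl", FALSE); kcl_c <- pick("KCl", TRUE)
  if (is.null(nacl) || is.null(nacl_c) || is.null(kcl) || is.null(kcl_c))
    stop_data("need NaCl and KCl slopes both with and without CCCP")
  enhanced <- function(a, b)   # b vs a: larger magnitude, same direction
    sign(a$slope) == sign(b$slope) &&
      abs(b$slope) >= (1 + rel_change) * abs(a$slope)
  diminished <- function(a, b) # b vs a: magnitude moved toward zero
    abs(b$slope) <= (1 - rel_change) * abs(a$slope)

  na2so4 <- pick("Na2SO4", FALSE)
  anion_ok <- is.null(na2so4) || na2so4$sign == nacl$sign

  if (nacl$sign > 0 && enhanced(nacl, nacl_c) &&
      kcl$sign < 0 && diminished(kcl, kcl_c) && anion_ok) {
    verdict <- "sodium_pump"
    rationale <- paste(
      "alkalinization in NaCl enhanced by CCCP (secondary H+ uptake driven",
      "by electrogenic cation export), acidification in KCl diminished by",
      "CCCP (direct H+ export only without a transportable cation)",
      if (!is.null(na2so4)) "; Na2SO4 reproduces NaCl (anion-independent)"
      else "")
  } else if (nacl$sign < 0 && diminished(nacl, nacl_c)) {
    verdict <- "proton_pump"
    rationale <- paste("acidification in NaCl diminished by CCCP indicates",
                       "primary outward H+ transport")
  } else {
    verdict <- "inconclusive"
    rationale <- "slope pattern matches neither pump signature"
  }
  structure(list(verdict = verdict, rationale = rationale, slopes = tab),
            class = "transport_call")
}

#' @export
print.transport_call <- function(x, ...) {
  cat(sprintf("<transport_call> %s\n  %s\n", x$verdict, x$rationale))
  invisible(x)
}

#' Bound the H+/Na+ flux ratio of a sodium pump
#'
#' Even a strictly Na+-selective uptake site passes some H+ because both
#' ions compete for it; the relative H+ flux is bounded by the ratio of the
#' ions' uptake rate constants divided by the ratio of their activities.
#' With a cytoplasmic Na+/H+ activity ratio of 320,000 and an H+/Na+
#' uptake-rate-constant ratio of 8,000-9,000, the H+ flux is below 3% of
#' the Na+ flux.
#'
#' @param activity_ratio Na+ activity divided by H+ activity (> 0).
#' @param rate_constant_ratio_range `c(low, high)` ratio of the H+ to Na+
#'   uptake rate constants (> 0).
#' @return A list of class `flux_ratio_bound`: `activity_ratio`,
#'   `rate_constant_ratio_range`, `bound_fraction` (interval),
#'   `bound_percent` (interval, %).
#' @export
flux_ratio_bound <- function(activity_ratio = 320000,
                             rate_constant_ratio_range = c(8000, 9000)) {
  check_scalar(activity_ratio, "activity_ratio", positive = TRUE)
  if (length(rate_constant_ratio_range) != 2 ||
      any(rate_constant_ratio_range <= 0))
    stop_param("rate_constant_ratio_range must be a positive interval")
  frac <- sort(rate_constant_ratio_range) / activity_ratio
  structure(list(activity_ratio = activity_ratio,
                 rate_constant_ratio_range = sort(rate_constant_ratio_range),
                 bound_fraction = frac,
                 bound_percent = 100 * frac),
            class = "flux_ratio_bound")
}

#' @export
print.flux_ratio_bound <- function(x, ...) {
  cat(sprintf(
    "<flux_ratio_bound> H+/Na+ flux ratio in [%.3g%%, %.3g%%]\n",
    x$bound_percent[1], x$bound_percent[2]))
  invisible(x)
}
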