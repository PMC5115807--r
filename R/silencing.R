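#' Construct a current-clamp voltage trace
#'
#' @param time Sample times (s), uniform grid.
#' @param potential Membrane potential (mV), junction-potential corrected.
#' @param injection_epoch Current-injection epoch `c(start, end)` (s).
#' @param light_epoch Light epoch `c(start, end)` (s), or `NULL` for the
#'   dark protocol.
#' @param sweep_id,neuron_id Labels.
#' @param junction_mv Optional liquid-junction potential (mV) to subtract
#'   for files that were not corrected at acquisition time.
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(time, potential, injection_epoch,
                          light_epoch = NULL, sweep_id = "sweep01",
                          neuron_id = "neuron1", junction_mv = 0) {
  if (length(time) != length(potential))
    stop_param("time and potential must have equal length")
  check_epoch(injection_epoch, "injection_epoch",
              t_min = time[1], t_max = time[length(time)])
  if (!is.null(light_epoch))
    check_epoch(light_epoch, "light_epoch",
                t_min = time[1], t_max = time[length(time)])
  structure(list(time = as.numeric(time),
                 potential = as.numeric(potential) - junction_mv,
                 injection_epoch = injection_epoch,
                 light_epoch = light_epoch,
                 sweep_id = sweep_id, neuron_id = neuron_id),
            class = "voltage_trace")
}

#' Detect action potentials by threshold crossing
#'
#' A spike is an upward crossing of `threshold`; crossings closer than
#' `refractory` to the previous accepted spike are ignored. The defaults
#' (-10 mV, 2 ms) separate full-height action potentials from subthreshold
#' fluctuations in typical current-clamp recordings.
#'
#' @param trace A [voltage_trace()].
#' @param threshold Crossing threshold (mV).
#' @param refractory Minimum interval between accepted spikes (s).
#' @return Numeric vector of spike times (s), strictly increasing.
#' @export
detect_spikes <- function(trace, threshold = -10, refractory = 0.002) {
  v <- trace$potential
  if (any(!is.finite(v))) stop_data("trace contains non-finite samples")
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  if (length(up) == 0) return(numeric(0))
  times <- trace$time[up]
  keep <- times[1]
  for (t in times[-1]) if (t - keep[length(keep)] >= refractory)
    keep <- c(keep, t)
  keep
}

#' Build a spike raster from sweeps
#'
#' @param spike_times A list of numeric vectors, one per sweep (order
#'   preserved), each strictly increasing.
#' @param protocol `"Dark"` or `"Light"`.
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(spike_times, protocol = c("Dark", "Light")) {
  protocol <- match.arg(protocol)
  for (st in spike_times)
    if (is.unsorted(st, strictly = TRUE))
      stop_param("spike times must be strictly increasing within a sweep")
  structure(list(spike_times = spike_times, protocol = protocol),
            class = "spike_raster")
}

#' Detect spikes across a whole experiment
#'
#' @param sweeps A list of [voltage_trace()]s.
#' @inheritParams detect_spikes
#' @inheritParams spike_raster
#' @return A [spike_raster()].
#' @export
raster_from_sweeps <- function(sweeps, threshold = -10, refractory = 0.002,
                               protocol = c("Dark", "Light")) {
  spike_raster(lapply(sweeps, detect_spikes, threshold = threshold,
                      refractory = refractory),
               protocol = match.arg(protocol))
}

#' Bin a spike raster into 1-s time zones
#'
#' Counts spikes per sweep in consecutive time zones and reports the mean
#' rate per zone across sweeps. Spikes outside the zone grid are counted in
#' no zone; their number is recorded in `n_outside`.
#'
#' @param raster A [spike_raster()].
#' @param zone_edges Bin edges (s), uniform 1-s bins by convention (e.g.
#'   `0:12`); a zone is the half-open interval `[edge_i, edge_{i+1})`.
#' @return A list of class `zone_stats`: `zone_edges`, `counts` (sweeps x
#'   zones matrix), `rate` (mean spikes/s per zone), `protocol`,
#'   `n_outside`.
#' @export
zone_rates <- function(raster, zone_edges = 0:12) {
  if (length(zone_edges) < 2 || any(diff(zone_edges) <= 0))
    stop_param("zone_edges must be increasing with >= 2 edges")
  widths <- diff(zone_edges)
  n_zone <- length(widths)
  counts <- t(vapply(raster$spike_times, function(st) {
    zone <- findInterval(st, zone_edges, rightmost.closed = FALSE)
    tabulate(zone[zone >= 1 & zone <= n_zone &
                    st < zone_edges[length(zone_edges)]], nbins = n_zone)
  }, integer(n_zone)))
  if (n_zone == 1) counts <- matrix(counts, ncol = 1)
  n_outside <- sum(lengths(raster$spike_times)) - sum(counts)
  structure(list(zone_edges = zone_edges, counts = counts,
                 rate = colMeans(counts) / widths,
                 protocol = raster$protocol, n_outside = n_outside),
            class = "zone_stats")
}

#' Light/dark firing-frequency ratios over protocol windows
#'
#' For each analysis window (by convention before / during / after
#' irradiation), the ratio of total Light-protocol spikes to total
#' Dark-protocol spikes in that window. A ratio with a zero dark
#' denominator is undefined and flagged rather than computed.
#'
#' @param light,dark [zone_rates()] results for the Light and Dark
#'   protocols on identical zone grids.
#' @param windows Named list of `c(from, to)` windows (s). The default
#'   marks zones 0-1 s as before, 1-11 s as during, and 11-12 s as after
#'   irradiation; use `silencing_windows("late_onset")` for the 2-11 s
#'   irradiation-window variant.
#' @return A data.frame with one row per window: `window`, `light_spikes`,
#'   `dark_spikes`, `ratio`, `defined`.
#' @export
light_dark_ratios <- function(light, dark, windows = silencing_windows()) {
  if (!identical(light$zone_edges, dark$zone_edges))
    stop_data("light and dark zone grids differ")
  edges <- light$zone_edges
  out <- lapply(names(windows), function(nm) {
    w <- windows[[nm]]
    zi <- which(edges[-length(edges)] >= w[1] & edges[-1] <= w[2])
    if (length(zi) == 0) stop_data("window ", nm, " covers no zones")
    ls <- sum(light$counts[, zi])
    ds <- sum(dark$counts[, zi])
    data.frame(window = nm, light_spikes = ls, dark_spikes = ds,
               ratio = if (ds > 0) ls / ds else NA_real_,
               defined = ds > 0)
  })
  do.call(rbind, out)
}

#' Standard analysis windows for the silencing protocol
#'
#' `"standard"` takes the irradiation window as 1-11 s (light onset at the
#' 1-s zone boundary); `"late_onset"` takes it as 2-11 s. Both conventions
#' appear in practice depending on where light onset falls relative to the
#' zone grid, so both are provided.
#'
#' @param variant `"standard"` or `"late_onset"`.
#' @return A named list of `c(from, to)` windows (s).
#' @export
silencing_windows <- function(variant = c("standard", "late_onset")) {
  variant <- match.arg(variant)
  if (variant == "standard")
    list(before = c(0, 1), during = c(1, 11), after = c(11, 12))
  else
    list(before = c(0, 1), during = c(2, 11), after = c(11, 12))
}

#' Detect post-light rebound firing
#'
#' Compares the firing rate in the first second after light offset with the
#' pre-light baseline rate; rebound is called when the post-light rate
#' exceeds `factor` times the baseline.
#'
#' @param stats A [zone_rates()] result for the Light protocol.
#' @param light_epoch Light epoch `c(on, off)` (s).
#' @param factor Rate multiple required to call a rebound.
#' @return A list with `baseline_rate`, `rebound_rate`, `rebound` (logical).
#' @export
detect_rebound <- function(stats, light_epoch, factor = 1.5) {
  edges <- stats$zone_edges
  pre <- which(edges[-1] <= light_epoch[1])
  post <- which(edges[-length(edges)] >= light_epoch[2] &
                  edges[-1] <= light_epoch[2] + 1)
  if (length(pre) == 0 || length(post) == 0)
    stop_data("zone grid does not cover pre-light and post-light windows")
  baseline <- mean(stats$rate[pre])
  rebound <- mean(stats$rate[post])
  list(baseline_rate = baseline, rebound_rate = rebound,
       rebound = rebound > factor * baseline)
}
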