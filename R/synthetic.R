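# Seedable generators for every input the pipeline consumes. All generators
# are pure functions of (parameters, seed): the same call gives bit-identical
# output. Seeding is local (withr-style restore) so generators do not disturb
# the caller's RNG stream.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Generate a synthetic pump photocurrent trace
#'
#' Emulates the canonical outward pump photocurrent: zero baseline, rapid
#' activation to a peak after light onset, partial inactivation toward a
#' steady level during the pulse, and exponential deactivation back to
#' baseline after light offset. Amplitudes are specified as current
#' densities (pA/pF); the stored current is in pA (density times
#' capacitance), matching what an amplifier records.
#'
#' The peak envelope is `peak_amplitude * (1 - exp(-(t - light_on)/tau_act))`
#' and inactivation relaxes multiplicatively from 1 to `steady_fraction`
#' with time constant `tau_inact`, starting once activation has essentially
#' completed (5 activation time constants), so the generated peak density
#' approaches `peak_amplitude` and the steady level is exactly
#' `steady_fraction * peak_amplitude`.
#'
#' @param peak_amplitude Peak current density (pA/pF, >= 0, outward
#'   positive).
#' @param steady_fraction Steady-state level as a fraction of the peak, in
#'   \[0, 1\].
#' @param tau_act,tau_inact,tau_deact Activation, inactivation and
#'   deactivation time constants (s, > 0). Defaults give the fast-on,
#'   slow-inactivating, fast-off shape typical of NaR photocurrents at
#'   10 kHz sampling.
#' @param capacitance Whole-cell capacitance (pF).
#' @param light_on,light_off Light epoch (s).
#' @param duration Record length (s); defaults to `light_off + 0.2`.
#' @param sample_rate Sampling rate (Hz).
#' @param noise_sd Gaussian noise s.d. in density units (pA/pF).
#' @param irradiance,wavelength_band,holding_potential Metadata carried on
#'   the trace.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#'
#' @return A [photocurrent_trace()].
#' @export
gen_photocurrent_trace <- function(peak_amplitude, steady_fraction,
                                   tau_act = 0.005, tau_inact = 0.1,
                                   tau_deact = 0.01,
                                   capacitance = 30,
                                   light_on = 0.1, light_off = 1.1,
                                   duration = light_off + 0.2,
                                   sample_rate = 10000,
                                   noise_sd = 0,
                                   irradiance = NA_real_,
                                   wavelength_band = NA_real_,
                                   holding_potential = 0,
                                   seed = NULL) {
  check_scalar(peak_amplitude, "peak_amplitude", nonneg = TRUE)
  check_scalar(steady_fraction, "steady_fraction")
  if (steady_fraction < 0 || steady_fraction > 1)
    stop_param("steady_fraction must lie in [0, 1]")
  for (nm in c("tau_act", "tau_inact", "tau_deact", "sample_rate",
               "capacitance"))
    check_scalar(get(nm), nm, positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_epoch(c(light_on, light_off), "light epoch", t_min = 0,
              t_max = duration)

  time <- seq(0, duration, by = 1 / sample_rate)
  density <- numeric(length(time))
  lit <- time >= light_on & time < light_off
  tl <- time[lit] - light_on
  act <- 1 - exp(-tl / tau_act)
  t_delay <- 5 * tau_act
  inact <- steady_fraction + (1 - steady_fraction) *
    exp(-pmax(0, tl - t_delay) / tau_inact)
  density[lit] <- peak_amplitude * act * inact
  post <- time >= light_off
  if (any(lit)) {
    d_off <- density[lit][sum(lit)]
    density[post] <- d_off * exp(-(time[post] - light_off) / tau_deact)
  }
  density <- density + with_seed(seed, stats::rnorm(length(time), 0, noise_sd))
  photocurrent_trace(time, density * capacitance, capacitance,
                     light_on, light_off, irradiance = irradiance,
                     wavelength_band = wavelength_band,
                     holding_potential = holding_potential)
}

#' Construct a dose-response data set
#'
#' @param irradiance Irradiances (mW/mm^2), strictly positive.
#' @param response Responses (pA/pF), same length.
#' @param cell_id Label for the cell the points came from.
#' @return An object of class `dose_response`.
#' @export
dose_response <- function(irradiance, response, cell_id = "cell1") {
  if (length(irradiance) == 0) stop_param("irradiance list must be non-empty")
  if (length(irradiance) != length(response))
    stop_param("irradiance and response must have equal length")
  if (any(!is.finite(irradiance)) || any(irradiance <= 0))
    stop_param("irradiances must be finite and > 0")
  structure(list(irradiance = as.numeric(irradiance),
                 response = as.numeric(response),
                 cell_id = cell_id),
            class = "dose_response")
}

#' Michaelis-Menten and suppression-subtracted response models
#'
#' `mm_response()` is the saturating hyperbola `imax * x / (x + kd)`.
#' `suppressed_mm_response()` subtracts a second saturating component that
#' switches on above a threshold irradiance, modelling the high-power
#' photocurrent suppression seen in some pumps:
#' `imax*x/(x+kd1) - supp_amp*(x-T)/((x-T)+kd2)` for `x > T`.
#'
#' @param x Irradiance (mW/mm^2).
#' @param imax Saturating amplitude (pA/pF).
#' @param kd,kd1,kd2 Half-saturation irradiances (mW/mm^2), > 0.
#' @param supp_amp Suppression amplitude (pA/pF), >= 0.
#' @param threshold Irradiance above which suppression engages (mW/mm^2).
#' @return Model value(s), same length as `x`.
#' @export
mm_response <- function(x, imax, kd) imax * x / (x + kd)

#' @rdname mm_response
#' @export
suppressed_mm_response <- function(x, imax, kd1, supp_amp, threshold, kd2) {
  xs <- pmax(x - threshold, 0)
  mm_response(x, imax, kd1) - supp_amp * xs / (xs + kd2)
}

#' Generate synthetic dose-response data sets
#'
#' Draws per-cell irradiance-response points from a Michaelis-Menten curve
#' (optionally with the above-threshold suppression component subtracted)
#' with multiplicative Gaussian noise of coefficient of variation
#' `noise_cv`.
#'
#' @param imax,kd Generating hyperbola parameters.
#' @param irradiances Irradiance grid (mW/mm^2, > 0).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param suppression Optional `c(amp, threshold, kd2)` for the suppression
#'   component.
#' @param n_cells Number of independent cells to simulate.
#' @param seed Integer seed or `NULL`.
#' @return A list of [dose_response()] objects, one per cell.
#' @export
gen_dose_response <- function(imax, kd, irradiances, noise_cv = 0,
                              suppression = NULL, n_cells = 1, seed = NULL) {
  if (length(irradiances) == 0) stop_param("irradiance list must be non-empty")
  check_scalar(kd, "kd", positive = TRUE)
  if (any(irradiances <= 0)) stop_param("irradiances must be > 0")
  check_scalar(noise_cv, "noise_cv", nonneg = TRUE)
  mu <- if (is.null(suppression)) {
    mm_response(irradiances, imax, kd)
  } else {
    if (length(suppression) != 3)
      stop_param("suppression must be c(amp, threshold, kd2)")
    suppressed_mm_response(irradiances, imax, kd,
                           suppression[1], suppression[2], suppression[3])
  }
  with_seed(seed, {
    lapply(seq_len(n_cells), function(i) {
      y <- mu * (1 + stats::rnorm(length(mu), 0, noise_cv))
      dose_response(irradiances, y, cell_id = sprintf("cell%02d", i))
    })
  })
}

#' Generate a synthetic normalized current-voltage series
#'
#' Produces a normalized I-V relationship that is linear in voltage,
#' `1 + slope_neg * V`, anchored at exactly 1 at 0 mV before noise. With a
#' positive `slope_neg` the normalized current falls at hyperpolarized
#' (negative) potentials, the signature voltage dependence of NaR pump
#' currents.
#'
#' @param slope_neg Generating slope in mV^-1 (e.g. `7.33e-3` for a slope of
#'   7.33 in the conventional 10^-3 mV^-1 units).
#' @param voltages Holding potentials (mV); must include 0.
#' @param noise_sd Additive Gaussian noise s.d. (normalized units).
#' @param seed Integer seed or `NULL`.
#' @return An [iv_series()] in normalized units.
#' @export
gen_iv_series <- function(slope_neg, voltages, noise_sd = 0, seed = NULL) {
  if (!any(voltages == 0)) stop_param("voltages must include 0 mV")
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  mu <- 1 + slope_neg * voltages
  y <- mu + with_seed(seed, stats::rnorm(length(mu), 0, noise_sd))
  iv_series(voltages, y, normalized = TRUE)
}

#' Generate a synthetic two-channel soma image
#'
#' Emulates a confocal slice through a soma: the membrane-marker (WGA role)
#' channel is a Gaussian annulus at the membrane; the reporter (eYFP role)
#' channel is either co-localized with the membrane ring (`"membrane"`),
#' aggregated in interior blobs (`"intracellular"`), or an equal mix
#' (`"mixed"`). Both channels are non-negative; noise is additive Gaussian
#' clipped at zero.
#'
#' @param image_size Side of the square image (pixels).
#' @param pixel_pitch Pixel size (um/pixel). The default matches a lag of 3
#'   pixels spanning 0.4 um, the lag range used by the overlapping index.
#' @param membrane_radius Membrane ring radius (um).
#' @param membrane_width Full width of the ring (um).
#' @param targeting_mode One of `"membrane"`, `"intracellular"`, `"mixed"`.
#' @param channel_gains Length-2 gains `c(reporter, marker)` (a.u.).
#' @param n_blobs Number of interior aggregates in intracellular/mixed mode.
#' @param noise_sd Additive noise s.d. (a.u.).
#' @param seed Integer seed or `NULL`.
#' @return A [two_channel_image()] with the centroid at the ring center.
#' @export
gen_soma_image <- function(image_size = 61, pixel_pitch = 0.4 / 3,
                           membrane_radius = 3, membrane_width = 0.4,
                           targeting_mode = c("membrane", "intracellular",
                                              "mixed"),
                           channel_gains = c(1, 1), n_blobs = 4,
                           noise_sd = 0, seed = NULL) {
  targeting_mode <- match.arg(targeting_mode)
  check_scalar(pixel_pitch, "pixel_pitch", positive = TRUE)
  check_scalar(membrane_radius, "membrane_radius", positive = TRUE)
  check_scalar(membrane_width, "membrane_width", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  ctr <- (image_size + 1) / 2
  half_um <- (ctr - 1) * pixel_pitch
  if (membrane_radius + membrane_width > half_um)
    stop_param("membrane ring exceeds the image frame")

  rc <- expand.grid(row = seq_len(image_size), col = seq_len(image_size))
  dist_um <- sqrt((rc$row - ctr)^2 + (rc$col - ctr)^2) * pixel_pitch
  sigma <- membrane_width / 2
  ring <- matrix(exp(-(dist_um - membrane_radius)^2 / (2 * sigma^2)),
                 image_size, image_size)

  with_seed(seed, {
    blobs <- matrix(0, image_size, image_size)
    if (targeting_mode != "membrane") {
      for (b in seq_len(n_blobs)) {
        theta <- stats::runif(1, 0, 2 * pi)
        r <- stats::runif(1, 0, 0.55 * membrane_radius)
        br <- ctr + r * cos(theta) / pixel_pitch
        bc <- ctr + r * sin(theta) / pixel_pitch
        bs <- stats::runif(1, 0.25, 0.5)  # um
        d2 <- (rc$row - br)^2 + (rc$col - bc)^2
        blobs <- blobs + matrix(exp(-d2 * pixel_pitch^2 / (2 * bs^2)),
                                image_size, image_size)
      }
      blobs <- blobs / max(blobs)
    }
    reporter <- switch(targeting_mode,
                       membrane = ring,
                       intracellular = blobs,
                       mixed = 0.5 * ring + 0.5 * blobs)
    reporter <- channel_gains[1] * reporter
    marker <- channel_gains[2] * ring
    if (noise_sd > 0) {
      reporter <- pmax(reporter +
        matrix(stats::rnorm(image_size^2, 0, noise_sd), image_size), 0)
      marker <- pmax(marker +
        matrix(stats::rnorm(image_size^2, 0, noise_sd), image_size), 0)
    }
    two_channel_image(reporter, marker, pixel_pitch,
                      centroid = c(round(ctr), round(ctr)))
  })
}

#' Generate a synthetic current-clamp silencing experiment
#'
#' Emulates the optogenetic silencing protocol: repeated sweeps of square
#' current injection drive tonic firing; a light pulse inside the injection
#' epoch hyperpolarizes the cell and suppresses firing; firing transiently
#' rebounds for one second after light offset. Spikes are drawn as a
#' piecewise-homogeneous Poisson process (rate `baseline_rate` during
#' injection, `silenced_rate` during light, `rebound_rate` for 1 s after
#' light) with a 5-ms minimum inter-spike interval, and rendered as
#' stereotyped 2-ms triangular events of +80 mV on the membrane-potential
#' baseline. Ground-truth spike times are returned alongside the traces.
#'
#' @param sweep_count Number of sweeps (>= 1).
#' @param duration Sweep length (s).
#' @param injection_epoch Current-injection epoch `c(start, end)` (s).
#' @param light_epoch Light epoch `c(start, end)` (s) or `NULL` for the dark
#'   protocol.
#' @param baseline_rate,silenced_rate,rebound_rate Firing rates (spikes/s,
#'   >= 0) in the corresponding zones.
#' @param rmp Resting membrane potential (mV).
#' @param depolarization Depolarization due to current injection (mV).
#' @param hyperpolarization Light-evoked hyperpolarization (mV, >= 0).
#' @param sample_rate Sampling rate (Hz).
#' @param noise_sd Membrane-potential noise s.d. (mV).
#' @param neuron_id Label attached to each sweep.
#' @param seed Integer seed or `NULL`.
#' @return A list with `sweeps` (list of [voltage_trace()]) and
#'   `ground_truth` (list of spike-time vectors), of class
#'   `silencing_experiment`.
#' @export
gen_silencing_experiment <- function(sweep_count = 10, duration = 12.5,
                                     injection_epoch = c(0, 12),
                                     light_epoch = c(1, 11),
                                     baseline_rate = 10, silenced_rate = 0,
                                     rebound_rate = 20,
                                     rmp = -65, depolarization = 15,
                                     hyperpolarization = 10,
                                     sample_rate = 10000, noise_sd = 0.3,
                                     neuron_id = "neuron1", seed = NULL) {
  if (sweep_count < 1) stop_param("sweep_count must be >= 1")
  for (nm in c("baseline_rate", "silenced_rate", "rebound_rate"))
    check_scalar(get(nm), nm, nonneg = TRUE)
  check_epoch(injection_epoch, "injection_epoch", t_min = 0, t_max = duration)
  if (!is.null(light_epoch)) {
    check_epoch(light_epoch, "light_epoch", t_min = 0, t_max = duration)
    if (light_epoch[1] < injection_epoch[1] ||
        light_epoch[2] > injection_epoch[2])
      stop_param("light_epoch must lie within injection_epoch")
  }

  # rate segments inside the injection epoch
  segs <- if (is.null(light_epoch)) {
    data.frame(from = injection_epoch[1], to = injection_epoch[2],
               rate = baseline_rate)
  } else {
    reb_end <- min(light_epoch[2] + 1, injection_epoch[2])
    data.frame(
      from = c(injection_epoch[1], light_epoch[1], light_epoch[2], reb_end),
      to   = c(light_epoch[1], light_epoch[2], reb_end, injection_epoch[2]),
      rate = c(baseline_rate, silenced_rate, rebound_rate, baseline_rate))
  }
  segs <- segs[segs$to > segs$from, , drop = FALSE]

  time <- seq(0, duration, by = 1 / sample_rate)
  min_isi <- 0.005
  spike_len <- 0.002

  with_seed(seed, {
    ground_truth <- vector("list", sweep_count)
    sweeps <- vector("list", sweep_count)
    for (s in seq_len(sweep_count)) {
      st <- unlist(lapply(seq_len(nrow(segs)), function(i) {
        n <- stats::rpois(1, segs$rate[i] * (segs$to[i] - segs$from[i]))
        if (n == 0) return(numeric(0))
        sort(stats::runif(n, segs$from[i], segs$to[i]))
      }))
      st <- sort(st)
      if (length(st) > 1) {            # enforce the minimum ISI by thinning
        keep <- c(TRUE, diff(st) >= min_isi)
        while (!all(keep)) {
          st <- st[keep]
          keep <- c(TRUE, diff(st) >= min_isi)
        }
      }
      v <- rep(rmp, length(time))
      inj <- time >= injection_epoch[1] & time < injection_epoch[2]
      v[inj] <- v[inj] + depolarization
      if (!is.null(light_epoch)) {
        lit <- time >= light_epoch[1] & time < light_epoch[2]
        v[lit] <- v[lit] - hyperpolarization
      }
      for (t0 in st) {                 # triangular waveform, peak +80 mV
        idx <- which(time >= t0 & time < t0 + spike_len)
        if (length(idx) > 0) {
          ph <- (time[idx] - t0) / (spike_len / 2)
          v[idx] <- v[idx] + 80 * ifelse(ph <= 1, ph, pmax(2 - ph, 0))
        }
      }
      if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
      ground_truth[[s]] <- st
      sweeps[[s]] <- voltage_trace(time, v, injection_epoch, light_epoch,
                                   sweep_id = sprintf("sweep%02d", s),
                                   neuron_id = neuron_id)
    }
    structure(list(sweeps = sweeps, ground_truth = ground_truth,
                   light_epoch = light_epoch,
                   injection_epoch = injection_epoch),
              class = "silencing_experiment")
  })
}

#' Generate a synthetic pH-assay trace
#'
#' Emulates the suspension pH measurement used to classify pump ion
#' transport in E. coli: pH is flat before illumination, drifts linearly
#' during the light epoch, and holds afterwards. In NaCl or Na2SO4 the
#' drift is upward (secondary H+ uptake driven by electrogenic Na+ export)
#' and is steepened by the protonophore CCCP; in KCl the drift is downward
#' (direct H+ export when no transportable cation is available) and is
#' flattened toward zero by CCCP.
#'
#' @param condition One of `"NaCl"`, `"Na2SO4"`, `"KCl"`.
#' @param cccp Logical: protonophore present?
#' @param light_epoch Illumination epoch (s).
#' @param duration Record length (s).
#' @param sample_rate Sampling rate (Hz).
#' @param ph0 Starting pH.
#' @param noise_sd pH noise s.d.
#' @param seed Integer seed or `NULL`.
#' @return A [ph_trace()].
#' @export
gen_ph_trace <- function(condition = c("NaCl", "Na2SO4", "KCl"),
                         cccp = FALSE, light_epoch = c(120, 300),
                         duration = 360, sample_rate = 1, ph0 = 7.0,
                         noise_sd = 0.002, seed = NULL) {
  condition <- match.arg(condition)
  check_epoch(light_epoch, "light_epoch", t_min = 0, t_max = duration)
  # illumination-epoch drift rates in pH/min
  slope <- switch(condition,
                  NaCl   = if (cccp) 0.10 else 0.04,
                  Na2SO4 = if (cccp) 0.09 else 0.035,
                  KCl    = if (cccp) -0.005 else -0.03)
  time <- seq(0, duration, by = 1 / sample_rate)
  drift <- pmin(pmax(time - light_epoch[1], 0),
                light_epoch[2] - light_epoch[1]) * slope / 60
  ph <- ph0 + drift + with_seed(seed, stats::rnorm(length(time), 0, noise_sd))
  ph_trace(time, ph, light_epoch, condition, cccp)
}
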