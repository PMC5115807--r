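---
title: "Models and methods behind narpump"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind narpump}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(narpump)
```

narpump implements the quantitative workflow used to characterize
light-driven Na⁺-pump rhodopsins (NaRs) as optogenetic silencers. This
vignette documents the models, the tunable parameters and their defaults,
what the synthetic-data generators do and do not emulate, and the
numerical choices made where the methodology left room.

## Photocurrent traces and feature extraction

A pump photocurrent under a light pulse has three phases: fast activation
to a peak, partial inactivation toward a steady state, and deactivation
back to baseline after light offset. The features extracted are the peak
and steady-state current densities `i_p` and `i_ss` — amplitudes divided
by the whole-cell capacitance, which scales with membrane area, so
densities are comparable across cells — and the inactivation ratio
`(i_p - i_ss) / i_p`.

Choices a user may want to revisit:

* **Steady-state window** (`steady_window`, default 50 ms). The steady
  state is conventionally read "at the end" of the pulse; a mean over a
  short terminal window is unbiased once inactivation has equilibrated
  (time constants are ~100 ms against a 1-s pulse) and suppresses
  sample-level noise. The window is configurable because short pulses may
  need a shorter window.
* **Peak on a filtered copy.** The peak is located on a 1-ms boxcar
  (≈1-kHz low-pass) copy of the trace, mirroring the analogue filtering
  of typical recording hardware, so a single noise sample cannot define
  `i_p`. The boxcar slightly attenuates a true instantaneous peak (well
  under 1% for the default kinetics); tests budget for this.
* **Clamping.** A noise-driven negative `i_ss` is clamped to zero with a
  warning so the inactivation ratio stays in [0, 1]. The clamp is never
  silent.

The trace generator (`gen_photocurrent_trace`) uses an activation gate
`1 − exp(−t/τ_act)` multiplied by an inactivation relaxation from 1 to
`steady_fraction` with time constant `τ_inact` that starts after
`5 τ_act`, so the generated peak density approaches the nominal
`peak_amplitude` and the steady level equals
`steady_fraction × peak_amplitude` exactly. Defaults `τ_act` = 5 ms,
`τ_inact` = 100 ms, `τ_deact` = 10 ms at 10 kHz sampling reproduce the
fast-on / slowly-inactivating / fast-off shape of NaR photocurrents;
no published time constants were available for these pumps, so the values
encode the qualitative shape only.

## Irradiance-response models

Single-photon photocycles predict Michaelis–Menten saturation,
`I(x) = I_max·x/(x + K_D)`. Some pumps additionally lose steady-state
current at high power; that is modelled by subtracting a second
hyperbola that engages above a threshold `T`:

`I(x) = I_max·x/(x+K_D1) − A·(x−T)/((x−T)+K_D2)·1[x>T]`,

with `T` fixed at 10 mW/mm² (a given of the protocol, not a free
parameter). Below `T` the composite equals the plain hyperbola exactly,
and at `x = T` the suppression term is zero, so the model is continuous.
A restricted-range variant (`fit_kd_restricted`, default 0–12 mW/mm²)
fits the plain hyperbola only where both pump classes are hyperbolic,
making `K_D` values comparable between them.

Fitting is bounded nonlinear least squares with multi-start
initialization: `imax` starts at the maximum response, `kd` at the
irradiance nearest half-maximal response and at the median irradiance;
composite fits additionally anchor their starting hyperbola on the
sub-threshold points. Each start is run through both Levenberg–Marquardt
(`minpack.lm::nlsLM`) and the port trust-region algorithm (`nls`),
keeping the converged fit with the smallest residual sum of squares —
the two optimizers have complementary failure modes (LM's rank check can
reject nested models whose suppression amplitude is truly zero; port
occasionally stalls on plateaus LM crosses). Bounds are physical:
amplitudes in [0, 10 × max response], `kd` in [10⁻³, 10⁴] mW/mm². A `kd`
that runs to its lower bound (saturated, constant responses) is flagged
as a boundary fit rather than reported as a real half-saturation. A
fitted composite that dips below zero inside the data range is flagged
(`negative_values`), never clamped.

Per-cell fits are first-class; `summarize_fits` gives the mean ± SEM
across cells. Pooled fits are obtained by concatenating cells into one
`dose_response` — both routes are exposed because conventions differ on
whether published curves are pooled or averaged per cell.

## Voltage dependence and action spectra

I–V series are expressed relative to the 0-mV current (`normalize_iv`,
idempotent, exact 1 at 0 mV). `S_neg` is the ordinary least-squares slope
through the points at `V ≤ 0`, reported in 10⁻³ mV⁻¹: normalized currents
change by a few tenths over 80 mV, so slopes of order 4–7 in these units
are typical. The 0-mV anchor is included by default (`include_zero`)
because published I–V plots run to 0 mV; an exclusion flag covers the
stricter reading of "negative region". The printed unit convention
"10³ mV⁻¹" seen in some tables is interpreted as 10⁻³ mV⁻¹ — a slope of
order 10³ per mV is physically impossible for a normalized current.

Action spectra divide each cell's steady-state photocurrent by the
irradiance delivered at that wavelength (power-density correction, the
stated convention), normalize to the per-cell maximum, then average
across cells. A photon-flux correction (divide by irradiance × λ) is
provided but off by default, since the power-density wording is
explicit. Per-cell normalization makes the result invariant to
expression-level differences between cells.

## The overlapping index

Membrane targeting is quantified along the horizontal and vertical lines
through the soma centroid. The marker (WGA) profile is bounded by the
first samples from each end that reach half its global maximum — the
half-peak points just outside the membrane — and both profiles are
restricted to that segment. For each axis and each pixel lag
`k ∈ {0, ±1, ±2, ±3}`, the Pearson correlation between the reporter
segment and the marker segment shifted by `k` is computed over their
overlapping support (truncation, no wraparound — wraparound would
correlate opposite membrane edges); the index is the mean of the 14
coefficients.

Numerical choices:

* **Pearson per lag, not a sliding dot product.** Only a normalized
  per-lag coefficient is bounded in [−1, 1], which the ±1 interpretation
  of the index requires. Consequently the index is invariant to positive
  affine rescaling of either channel, and swapping channels maps lag `k`
  to `−k`, leaving the mean unchanged — both properties are tested
  exactly.
* **The +1 ceiling is a bound, not an attained value.** Even perfectly
  co-localized channels give nonzero-lag coefficients equal to profile
  autocorrelations, which are < 1 for any non-constant profile, so
  identical channels give an index close to but below 1 (about 0.94 for
  a smooth unimodal segment). The implementation reports what the
  definition produces and does not force the value.
* **Lags are integer pixels.** ±3 pixels corresponds to ±0.4 µm at a
  pixel pitch of ~0.133 µm/pixel; a warning is issued when the supplied
  pitch puts lag 3 more than 25% away from 0.4 µm.
* **Centroid.** Supplied explicitly or computed as the marker-channel
  intensity centroid; line profiles are the centroid's pixel row and
  column.
* Segments shorter than 8 samples (lag 3 would leave fewer than 5
  overlapping points) and zero-variance segments are errors, not NAs.

The image generator draws a Gaussian annulus for the marker and either
the same annulus (membrane mode), interior Gaussian blobs
(intracellular mode) or a mix for the reporter. On these phenotypes the
index separates cleanly (≈0.7 vs below 0.1); real confocal slices add
out-of-focus light, uneven WGA staining and non-circular somata, so
real-data contrasts are expected to be smaller.

## Silencing analysis

Spikes are upward crossings of a −10 mV threshold separated by at least
2 ms; ground-truth recovery on rendered synthetic sweeps is ≥95% with no
false positives. Traces are assumed junction-potential corrected; the
`junction_mv` argument of `voltage_trace` applies the subtraction for
uncorrected files. Firing is binned into 1-s zones per sweep (counts are
conserved: per sweep, zone counts sum to the spikes inside the analysis
window, with out-of-window spikes counted and reported separately), and
Light/Dark spike-count ratios are computed over the before (0–1 s),
during (1–11 s) and after (11–12 s) irradiation windows. Because light
onset may fall on either side of a zone boundary depending on the
protocol, a `late_onset` variant (during = 2–11 s) is provided;
neither is privileged. A zero dark denominator yields an undefined,
flagged ratio — never an infinity.

The exact rank tests enumerate the full reference distribution via the
shift (subset-sum convolution) algorithm on doubled midranks, which
handles ties exactly; doubling makes half-integer midranks integral.
Exact enumeration is used up to a combined n of 25 (signed-rank: 25
nonzero differences), beyond which the tie-corrected normal
approximation with continuity correction takes over. Two-sided p is
twice the smaller one-sided tail, capped at 1. Brute-force enumeration
(`combn` over rank assignments, `expand.grid` over sign patterns) serves
as the oracle in tests for every layout up to combined n = 10, and
`stats::wilcox.test` provides an independent cross-check in the tie-free
exact and large-sample regimes.

The silencing generator draws spikes as a piecewise-homogeneous Poisson
process (baseline during injection, silenced during light, rebound for
1 s after light) thinned to a 5-ms minimum inter-spike interval, and
renders each spike as a fixed 2-ms triangular +80 mV event — only
crossing times matter downstream, so no conductance-based neuron model
is attempted. Real neurons show adapting rates, spike-height rundown and
noise-correlated excitability that the generator does not emulate;
passing tests demonstrate the analysis chain, not neuronal realism.

## Transport classification and the flux-ratio bound

The light-induced pH slope is the least-squares slope over the central
80% of the illumination epoch (avoiding onset/offset transients) minus
the pre-light baseline slope, in pH/min, with a ±0.005 pH/min dead band
for the sign call. The verdict logic encodes the standard suspension
assay: an outward Na⁺ pump alkalinizes NaCl (secondary H⁺ uptake driven
by electrogenic Na⁺ export, enhanced by CCCP) and acidifies KCl (direct
H⁺ export when no transportable cation is present, short-circuited by
CCCP); Na₂SO₄ reproducing NaCl confirms anion independence. The mirror
pattern (NaCl acidification diminished by CCCP) calls a proton pump;
anything else is inconclusive. "Enhanced"/"diminished" is a ≥25%
relative slope-magnitude change — the qualitative descriptions this
encodes give no sharper number, and the threshold is exposed as
`rel_change`.

The flux-ratio bound divides the H⁺/Na⁺ uptake-rate-constant ratio by
the cytoplasmic Na⁺/H⁺ activity ratio: with 8,000–9,000 and 320,000 the
relative H⁺ flux is 2.50–2.81%, strictly below 3%. The bound is
homogeneous of degree zero — scaling both ratios together changes
nothing — which the tests assert.

## Chimera construction

Sequences are partitioned into seven TMD segments by six 1-based
junction indices per parent (`split_domains` always reassembles to the
input exactly). A junction-`k` chimera takes residues 1 to the
N-parent's junction-`k` end and the C-parent's residues from its
junction-`k` resumption start onward. The published junction tables give
each parent its own boundary set (the parents' numbering is offset by
alignment), and under the printed ranges one residue of each parent is
skipped at every join; the builder follows the printed ranges literally
rather than forcing full coverage, and records each parent's residue
contribution as attributes. When two parents share a TMD exactly, the
chimeras that differ only by that TMD's junction are identical proteins
— a property the tests verify.

## Problem sizes and determinism

Validation uses 200 replicate noisy datasets per dose-response recovery
(5% multiplicative noise on a 7-point irradiance grid), a 198-point
noiseless dense grid for the composite fit, 1,000 fuzzed profile pairs
for the overlapping-index bound, 200 replicates for the noisy `S_neg`
recovery, and exhaustive rank-test layouts to combined n = 10 — sizes at
which the stochastic medians are stable to a few percent while the whole
suite runs in well under a minute per stage. All generators are pure
functions of (parameters, seed), restore the caller's RNG state, and are
bit-reproducible.

## Known limitations

* No photocycle kinetics: activation/inactivation time constants are not
  fitted, and the suppression component is phenomenological, not
  mechanistic.
* Colocalization is 1-D along two axes of a single slice — no z-stacks,
  no Manders/whole-image Pearson alternatives.
* The classifier consumes slope signs and magnitudes only; it does not
  model buffer capacity or membrane-potential dynamics of the bacterial
  suspension.
* Chimera design is sequence arithmetic; no structural or codon-level
  modelling.
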