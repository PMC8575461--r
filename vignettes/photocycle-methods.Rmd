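---
title: "Models and methods: photocycle kinetics, global fitting, and caged-substrate turnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: photocycle kinetics, global fitting, and caged-substrate turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhodokin)
```

## The system and the model

Rhodopsin guanylyl cyclases are light-activated enzymes: a microbial
rhodopsin domain absorbs a green photon, runs through a photocycle of
spectrally distinct intermediates, and the long-lived, blue-shifted M
intermediate switches on a guanylyl cyclase that converts GTP to cGMP.
This package models that photocycle as a closed four-state first-order
scheme

    D -> K -> L -> { M -> D | D }

with the dark state D, a fast red-shifted K intermediate, the L state,
and the deprotonated-Schiff-base M state. Photoexcitation enters as a
first-order D -> K rate `k_ex` that is nonzero only while actinic light
is on; a nanosecond flash is idealized as an instantaneous transfer of a
fraction `flash_conversion` of D into K. The L state can either proceed
to M (rate `k_LM`) or relax directly back to D (rate `k_LD`); setting
`k_LD = 0` gives the strictly sequential photocycle that describes the
room-temperature data.

The preset rate constants are the published lifetimes: for the slow-
cycling C259S mutant at 20 degrees C, tau_L = 1/k_LM = 40 ms and
tau_M = 1/k_MD = 3.13 s; for the wild type, 30 ms and 570 ms (a 5.5-fold
faster M decay). The -10 degrees C preset scales the C259S constants by
the observed temperature factors -- the total L decay 50-fold slower,
the M decay 10-fold slower -- and opens the L -> D branch with a default
branch fraction `k_LM / (k_LM + k_LD) = 0.5`, since at low temperature
both L decay paths have comparable rates.

Two generator parameters are deliberate fixtures rather than measured
values: the K decay (`k_KL = 1e4` 1/s) and the K absorption band
(560 nm). The K state is too fast to resolve at room temperature; all
that matters is that it is fast and red-shifted relative to D, and both
values are configurable. The flash conversion defaults to 0.3 (no
quantum yield is published; recovery results are invariant to this
overall scale because noise is specified relative to the signal).

```{r lifetimes}
eigen_time_constants(scheme_c259s_20C())
photostationary(scheme_c259s_20C(k_ex = 1))
```

Propagation solves dp/dt = A p piecewise per illumination segment via
the eigendecomposition of the 4x4 generator; if the eigenvector basis is
ill-conditioned (nearly repeated rates, relative gap below 1e-9) the
solver falls back to adaptive ODE integration (`deSolve`), which also
serves as the independent oracle in the test-suite (agreement to 1e-8
over random schemes). Trajectories are row-stochastic to 1e-9.

### A known tension in the photostationary state

With tau_M >> tau_L, any closed scheme of this shape accumulates M under
continuous illumination -- at -10 degrees C the stationary solution above
still favors M over L, whereas the measured low-temperature
photostationary mixture is reported to favor L. The experimental
observation hints at additional photochemistry ("light adaptation",
e.g. secondary photolysis of M) that is explicitly outside this model.
We keep the closed four-state scheme with the published branch fraction
and note that conclusions drawn from the simulated photostationary
*composition* (as opposed to the decay kinetics after illumination
stops, which are well described) should not be over-read.

## Synthetic data

The forward model for a dataset is bilinear: delta-A(t, x) =
populations(t, s) x species-spectra(s, x), plus noise. Species spectra
are sums of signed Gaussian bands (`a exp(-4 ln 2 (x - c)^2 / w^2)`);
Lorentzian or Voigt shapes are deliberately out of scope. Difference
spectra are light minus dark, so the D state contributes only through
negative bleach bands inside each intermediate's spectrum. Default
widths are 40 nm (UV-Vis) and 8 1/cm (FTIR); true widths and relative
amplitudes are figure-level information, so these are declared fixtures.
The retinal fingerprint bleaches at 1220/1198 1/cm are given equal
amplitude in every intermediate, which is what makes fingerprint-band
scaling (`scale_on_fingerprint`) a well-posed normalization.

Noise is i.i.d. Gaussian with standard deviation `sigma`, optionally
plus a slow exponential baseline drift per channel (amplitude drawn
uniformly per channel, one shared timescale); identical seeds give
bit-identical datasets. Study noise levels are specified relative to
the signal maximum (1% unless stated).

Default sampling emulates the instruments: rapid-scan FTIR frames every
29 ms; a log-spaced UV-Vis grid from 1 ms to 20 s (the flash experiment
brackets both lifetimes; the earliest sample sits after the unresolved
K decay); spectral axes of 2 nm (320--620 nm) and 1 1/cm
(1000--1800 1/cm; the stated instrumental resolution is 2 1/cm, and the
denser sampling mimics the usual interferogram zero-filling -- it also
lets band positions with odd wavenumbers be represented exactly).

What the generator does *not* emulate: water-vapor lines, detector
nonlinearity, structured (non-exponential) drift, rapid-scan artifacts,
photoselection/anisotropy, and any secondary photochemistry. Passing
recovery tests therefore demonstrate the correctness and calibration of
the analysis chain under the stated noise model, not robustness to every
artifact of real spectra.

## Preprocessing

* Baseline correction fits either a straight line (least squares over
  at least 2 anchor positions) or a smoothing spline (at least 4
  anchors) and subtracts it; the operation is idempotent. The published
  processing mentions a linear function and a "pre-spline"; we read the
  latter as a smoothing-spline baseline over user-chosen signal-free
  anchors applied before difference computation, and keep the mode
  explicit because the original algorithm is not specified.
* Smoothing is a centered N-point moving average with shrinking windows
  at the ends; even windows (8- and 18-point smoothing appear in the
  published figures) take the extra point on the trailing side. A moving
  average never increases the maximum absolute value of a trace.
* Fingerprint scaling equalizes the mean absolute amplitude at
  1220/1198 1/cm (nearest samples) against the first spectrum. A
  peak-to-peak statistic over a window was considered and rejected as
  more noise-sensitive.
* Dark-activity correction subtracts the least-squares line fitted over
  a pre-event window from the whole trace and reports the removed slope.

## SVD, global fitting, and target analysis

`svd_decompose` computes the plain SVD with a deterministic sign
convention (each spectral component's largest-magnitude element is
positive). Rank selection declares component i significant only if its
singular value is at least 1e-2 of the largest *and* its temporal vector
has |lag-1 autocorrelation| >= 0.5; the rank is the leading run of
significant components. The autocorrelation criterion is what lets a
pure-noise matrix report rank 0 even though its leading singular-value
ratio is 1; both thresholds are configurable, and a known noise sigma
optionally adds a Marchenko--Pastur-style singular-value floor
`sigma (sqrt(n) + sqrt(m))`.

`global_exponential_fit` fits shared time constants to all channels by
variable projection: for a candidate set of log time constants the
per-channel amplitudes (and optional per-channel constant offset,
fitted by default, representing any non-decaying photoproduct) are
solved exactly by linear least squares, and `nlminb` searches over the
log constants from a deterministic quantile start plus seeded random
multi-starts across roughly eight decades bracketing the time grid --
multi-exponential fitting is multi-modal, and the test-suite checks the
optimum against a dense two-dimensional grid search. By default the fit
runs on the rank-truncated temporal SVD components weighted by singular
values (the classic global-fit-of-SVD-components formulation), which is
numerically identical to raw-channel fitting at sufficient rank but much
cheaper; raw-channel fitting remains available. Components are reported
with ascending time constants.

`dads_to_sads` rotates decay-associated difference spectra (DADS) into
species-associated ones (SADS) under an assumed topology: the
concentration profiles are fixed linear combinations of the fitted
exponentials, C(t) = E(t) A, so SADS = A^-1 DADS exactly.

* Sequential: the cascade starting in the fastest species; A is the
  closed-form (Bateman) coefficient matrix fully determined by the
  fitted constants. Repeated constants are rejected (the cascade is
  defective there); in practice the multi-start fit never returns exact
  ties.
* Branched (two components): the post-illumination decay of an L/M
  mixture with the L -> D short-circuit. Two mixing parameters enter,
  the initial L fraction `alpha` and the branch fraction `b`. With
  freely fitted spectra a single dataset determines only the overlap
  combination c = alpha g / (1 - alpha + alpha g), g = b kL / (kL - kM)
  -- the classic rotational ambiguity. The default estimator finds c by
  minimal spectral overlap (the physical spectra are less mutually
  correlated than their mixtures) and resolves the leftover scale with
  an equal-norm convention between the two SADS, which is exact for the
  generator's band model and a reasonable prior for real amide-I
  difference spectra; both parameters can instead be fixed from
  independent knowledge, which is preferred when available.

`compare_topologies` makes the sequential-vs-branched question a proper
model comparison by jointly fitting one or more datasets with shared
spectra. Identifiability is subtle: all the mixing matrices involved are
triangular in the exponential basis, so if every dataset carries a free
amplitude scale, the branch fraction can be absorbed into a shared
spectral rescaling and the two topologies fit any pair of datasets
equally well. The implementation therefore anchors the scales
physically: flash datasets enter at their protocol's known flash
conversion, decay datasets get free initial L *and* M fractions (but no
extra scale). Under this design a flash + decay pair discriminates
cleanly -- sequential generators give equal residuals and the
information criterion (AICc) picks the thriftier sequential model;
branched generators impose a clear residual penalty on the sequential
fit. The branch fraction itself remains only set-identified from two
datasets; the comparison claims the topology class, not a precise b.

## Marker bands and steady state

Traces are extracted at stated band positions by snapping to the
nearest axis sample (FTIR axes are dense; interpolation would blur the
stated positions) with optional window averaging. Peak detection finds
local extrema of the requested sign with topographic prominence above a
threshold defaulting to three times the spectrum's median absolute
deviation. Steady state under continuous illumination is the first time
index after which the smoothed trace's relative slope (|d/dt| divided
by the trace maximum) stays below tolerance; for a saturating
exponential this reproduces the closed form t = tau ln(1/f). The onset
comparison between the M-state 1630(+) and product 1087(+) traces
dark-activity-corrects both, smooths (8 points), min-max normalizes
over the onset window, and reports the normalized RMS difference plus
the lag maximizing cross-correlation.

## Caged-substrate turnover

The enzyme experiment is a two-step protocol: the photolabile,
enzymatically inert NPE-GTP is loaded in the dark, a UV flash block
uncages it (releasing free GTP and the NAP by-product), and -- for the
light-gated holoenzyme -- green light later switches catalysis on. The
product trace model has:

* a constant dark-activity rate `v_dark` before light activation,
* no product step at uncaging (substrate only becomes available),
* during active phases, a first-order burst of the pre-bound substrate
  (`bound_amplitude`, `k_burst`) on top of a constant binding-limited
  rate `v_light`,
* a post-illumination rate `v_post` distinct from `v_dark` (production
  continues, slower, after light-off),
* optional product feedback inhibition scaling all rates by
  `1 / (1 + P / K_inhib)` -- a hyperbolic form chosen for its single
  interpretable constant, since only the existence of inhibition is
  suggested by the saturation behavior at 10-fold substrate,
* a hard mass-balance cap at `substrate_total` (integration terminates
  at the cap via a root finder rather than a discontinuous rate).

Phases without inhibition and away from the cap use closed forms. The
constitutively active cyclase domain is represented by a protocol whose
active phase starts at uncaging. The small post-light-off dip of the
product band (bound vs free product absorptivity) is not modeled by
default. `fit_phases` fits an independent line per protocol phase (no
continuity constraint, matching the usual constant-slope presentation),
and `fit_turnover` fits the full model by Levenberg--Marquardt with
non-negativity bounds and seeded multi-starts; `substrate_total` is a
fixed experimental input, not a fitted parameter.

In the synthetic enzyme datasets the burst rate defaults to a value
commensurate with the M-state rise under illumination, reflecting the
observed near-identical onset kinetics of the M and product markers
(product formation is gated by the catalytically active M state).

## Numerical choices and problem sizes

Optimizer starts, thresholds and seeds are fixed and recorded in every
result object; identical seeds reproduce results bit-identically. The
packaged studies use 20 replicate datasets per recovery experiment at 1%
relative noise, 160-point log time grids for UV-Vis (1 ms--20 s, or to
150 s for the -10 C variant), 29 ms FTIR frames to 140 s, and the
spectral axes above; the test-suite uses the same designs at reduced
sizes (fewer replicates, coarser axes) chosen so the whole suite runs
in well under a minute while still exercising every code path. Median
recovered constants sit within a fraction of a percent of the generator
truth; the 5% and 10% acceptance margins in the tests are dominated by
stochastic variation, not bias.

## Limitations

No Arrhenius temperature model (the two temperatures are independent
presets); no photochemical back-reactions or light adaptation; no
proton-transfer microsteps within M; no lifetime-distribution
(maximum-entropy) analysis; no instrument-response deconvolution; no
vendor file formats (a documented delimited-text format with metadata
sidecars is the interchange representation). The branched target
analysis reports convention-bound mixing parameters when they are not
fixed externally, as discussed above.
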