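#' Measurement noise model
#'
#' Additive i.i.d. Gaussian noise plus an optional slow exponential baseline
#' drift per spectral channel. With a fixed seed the generated dataset is
#' bit-identical across runs.
#'
#' @param sigma standard deviation of the Gaussian noise (delta-absorbance).
#' @param drift_amplitude maximum absolute drift amplitude per channel
#'   (delta-absorbance); channel amplitudes are drawn uniformly from
#'   `[-drift_amplitude, drift_amplitude]`.
#' @param drift_timescale drift time constant (s); each channel's baseline
#'   follows `a * (1 - exp(-t / drift_timescale))`.
#' @param seed integer RNG seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0, drift_amplitude = 0,
                        drift_timescale = 100, seed = 1L) {
  stopifnot_scalar_num(sigma, "sigma", lower = 0)
  stopifnot_scalar_num(drift_amplitude, "drift_amplitude", lower = 0)
  stopifnot_scalar_num(drift_timescale, "drift_timescale", lower = 0)
  structure(list(sigma = sigma, drift_amplitude = drift_amplitude,
                 drift_timescale = drift_timescale, seed = as.integer(seed)),
            class = "noise_model")
}

# drift (channel amplitudes drawn first) then noise; draw order is part of
# the determinism contract
apply_noise <- function(values, times, noise) {
  if (is.null(noise)) return(values)
  with_seed(noise$seed, {
    if (noise$drift_amplitude > 0) {
      amp <- stats::runif(ncol(values), -noise$drift_amplitude,
                          noise$drift_amplitude)
      shape <- 1 - exp(-(times - times[1L]) / noise$drift_timescale)
      values <- values + outer(shape, amp)
    }
    if (noise$sigma > 0) {
      values <- values + matrix(stats::rnorm(length(values), 0, noise$sigma),
                                nrow(values))
    }
    values
  })
}

#' Simulate a time-resolved difference-spectral dataset
#'
#' The bilinear forward model: delta-A(t, x) = populations(t, s) x
#' species-spectra(s, x), plus baseline drift and Gaussian noise. The dark
#' state D contributes no spectrum of its own (its bleach bands are part of
#' every intermediate's difference spectrum), so with everything in D the
#' dataset is zero.
#'
#' @param scheme a [kinetic_scheme()].
#' @param protocol an [illumination_protocol()].
#' @param species named list of [species_spectrum()] objects covering every
#'   populated non-dark state (see [default_species()]).
#' @param times output time grid (s).
#' @param axis spectral axis (nm or 1/cm, matching the species domain).
#' @param noise a [noise_model()], or `NULL` for a noiseless dataset.
#' @param init initial state fractions at `min(times)` (default all dark).
#' @return A [spectral_dataset()] whose `metadata` records the scheme,
#'   protocol, seed and the noiseless generator internals (population
#'   trajectory and species-spectrum matrix).
#' @export
simulate_dataset <- function(scheme, protocol, species, times, axis,
                             noise = noise_model(),
                             init = c(D = 1, K = 0, L = 0, M = 0)) {
  traj <- propagate(scheme, protocol, times, init = init)
  pops <- traj$populations
  active <- colnames(pops)[apply(abs(pops), 2L, max) > 1e-12]
  active <- setdiff(active, "D")
  missing <- setdiff(active, names(species))
  if (length(missing)) {
    stop("no species spectrum supplied for populated state(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  domain <- if (length(species)) species[[1L]]$domain else "uvvis"
  S <- matrix(0, ncol(pops), length(axis),
              dimnames = list(colnames(pops), NULL))
  for (nm in intersect(colnames(pops), names(species))) {
    if (nm == "D") next
    S[nm, ] <- render_spectrum(species[[nm]], axis)
  }
  values <- pops %*% S
  values <- apply_noise(values, times, noise)
  spectral_dataset(times, axis, values, domain = domain,
                   metadata = list(scheme = scheme, protocol = protocol,
                                   noise = noise,
                                   seed = if (!is.null(noise)) noise$seed,
                                   trajectory = traj, species_matrix = S))
}

#' Noise level as a fraction of the signal maximum
#'
#' Convenience for "sigma = x% of max delta-A" noise specifications: renders
#' the noiseless dataset and returns `fraction * max(abs(values))`.
#'
#' @inheritParams simulate_dataset
#' @param fraction noise level relative to the absolute signal maximum.
#' @return Numeric sigma (delta-absorbance units).
#' @export
relative_sigma <- function(scheme, protocol, species, times, axis,
                           fraction = 0.01,
                           init = c(D = 1, K = 0, L = 0, M = 0)) {
  ds <- simulate_dataset(scheme, protocol, species, times, axis,
                         noise = NULL, init = init)
  fraction * max(abs(ds$values))
}

#' Simulate a caged-substrate enzyme-turnover FTIR dataset
#'
#' Renders the marker-band content of the two-step uncaging experiment:
#' the caged-compound (NPE) bleach and the NAP by-product step at uncaging,
#' the substrate-binding doublet step, free-substrate (GTP) bands that
#' appear at uncaging and decline as substrate is turned over, product
#' (cGMP) bands following the turnover model trace, and the M-state 1630(+)
#' band following the photocycle population during green illumination.
#'
#' @param turnover a [turnover_params()] object.
#' @param protocol an [illumination_protocol()] containing a `uv` (uncaging)
#'   segment, e.g. [protocol_rgc_turnover()] or [protocol_gc_turnover()].
#' @param axis spectral axis (1/cm).
#' @param times output time grid (s).
#' @param noise a [noise_model()] or `NULL`.
#' @param species species band set, default [default_species]`("ftir-enzyme")`.
#' @param scheme photocycle scheme driving the M-state band under green
#'   light; default the slow-mutant scheme with `k_ex = 1`.
#' @return A [spectral_dataset()]; `metadata$traces` holds the generator's
#'   per-species kinetic traces (time x species matrix).
#' @export
simulate_enzyme_dataset <- function(turnover, protocol, axis, times,
                                    noise = noise_model(),
                                    species = default_species("ftir-enzyme"),
                                    scheme = scheme_c259s_20C(k_ex = 1)) {
  seg <- protocol$segments
  if (!any(seg$mode == "uv")) {
    stop("enzyme protocol must contain a uv (uncaging) segment", call. = FALSE)
  }
  t_uv <- min(seg$start[seg$mode == "uv"])
  step <- as.numeric(times >= t_uv)
  product <- simulate_turnover(turnover, protocol, times)
  frac <- if (is.finite(turnover$substrate_total) && turnover$substrate_total > 0) {
    pmin(product / turnover$substrate_total, 1)
  } else {
    # open-ended substrate pool: normalize to final product for band scaling
    if (max(product) > 0) product / max(product) else product
  }
  m_pop <- propagate(scheme, protocol, times)$populations[, "M"]

  traces <- cbind(
    cGMP    = frac,
    GTP     = step * (1 - frac),
    NPE     = step,
    NAP     = step,
    binding = step,
    M       = m_pop)
  S <- t(vapply(colnames(traces),
                function(nm) render_spectrum(species[[nm]], axis),
                numeric(length(axis))))
  values <- traces %*% S
  values <- apply_noise(values, times, noise)
  spectral_dataset(times, axis, values, domain = "ftir",
                   metadata = list(turnover = turnover, protocol = protocol,
                                   noise = noise,
                                   seed = if (!is.null(noise)) noise$seed,
                                   traces = traces, species_matrix = S,
                                   product = product))
}
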