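#' Gaussian spectral band
#'
#' A single signed Gaussian band of a difference spectrum. Positive
#' amplitudes are photoproduct gains, negative amplitudes dark-state
#' bleaches (difference spectra are light minus dark).
#'
#' @param center band position (nm for UV-Vis, 1/cm for FTIR).
#' @param amplitude signed peak delta-absorbance.
#' @param fwhm full width at half maximum, same unit as `center`; must be
#'   positive.
#' @return An object of class `spectral_band`.
#' @export
spectral_band <- function(center, amplitude, fwhm) {
  stopifnot_scalar_num(center, "center")
  stopifnot_scalar_num(amplitude, "amplitude")
  stopifnot_scalar_num(fwhm, "fwhm")
  if (fwhm <= 0) stop("'fwhm' must be > 0", call. = FALSE)
  structure(list(center = center, amplitude = amplitude, fwhm = fwhm),
            class = "spectral_band")
}

#' Species-associated difference spectrum
#'
#' The difference spectrum of one photocycle intermediate (or one chemical
#' species in the enzyme assay) as a sum of signed Gaussian bands. Because
#' difference spectra are light minus dark, the dark state D enters every
#' intermediate's spectrum as negative bleach bands and contributes no
#' spectrum of its own.
#'
#' @param species state or species label, e.g. `"L"`, `"M"`, `"cGMP"`.
#' @param bands list of [spectral_band()] objects.
#' @param domain `"uvvis"` or `"ftir"`.
#' @return An object of class `species_spectrum`.
#' @export
species_spectrum <- function(species, bands, domain = c("uvvis", "ftir")) {
  domain <- match.arg(domain)
  stopifnot(is.character(species), length(species) == 1L)
  if (!all(vapply(bands, inherits, logical(1), "spectral_band"))) {
    stop("'bands' must be a list of spectral_band objects", call. = FALSE)
  }
  structure(list(species = species, bands = bands, domain = domain),
            class = "species_spectrum")
}

#' Render a species spectrum on a spectral axis
#'
#' Sum of Gaussian bands `a * exp(-4 ln 2 (x - c)^2 / fwhm^2)` evaluated at
#' the axis samples. Linear in the band amplitudes; an empty band list gives
#' a zero vector.
#'
#' @param species a [species_spectrum()] or a list of [spectral_band()]s.
#' @param axis monotone numeric spectral axis.
#' @return Numeric vector of delta-absorbance, one value per axis sample.
#' @export
render_spectrum <- function(species, axis) {
  if (is.unsorted(axis) && is.unsorted(rev(axis))) {
    stop("'axis' must be monotone", call. = FALSE)
  }
  bands <- if (inherits(species, "species_spectrum")) species$bands else species
  y <- numeric(length(axis))
  for (b in bands) {
    y <- y + b$amplitude * exp(-4 * log(2) * ((axis - b$center) / b$fwhm)^2)
  }
  y
}

#' Default species spectra presets
#'
#' Band models for the three experimental read-outs.
#'
#' * `"uvvis-rgc"`: visible-range photocycle intermediates. Each
#'   intermediate carries its own absorption band (K 560 nm -- a fast,
#'   red-shifted placeholder, L 450 nm, M 350 nm) plus the 545 nm dark-state
#'   bleach; default FWHM 40 nm.
#' * `"ftir-rgc"`: amide-I marker bands of the photocycle intermediates
#'   (L: 1647(+)/1665(-); M: 1630(+)/1643(-)) plus shared retinal
#'   fingerprint bleaches at 1220(-)/1198(-) with equal amplitude across
#'   intermediates; default FWHM 8 1/cm.
#' * `"ftir-enzyme"`: caged-nucleotide turnover species -- cGMP
#'   1087(+)/1068(+), GTP 1122/923, the caged-compound (NPE) bleach
#'   1527(-)/1347(-), the NAP photolysis by-product 1686(+)/1267(+), the
#'   substrate-binding doublet 1070(+)/1117(-), and the M-state 1630(+)
#'   activation marker.
#'
#' Band positions are the published marker positions; widths and relative
#' amplitudes are generator fixtures.
#'
#' @param preset one of `"uvvis-rgc"`, `"ftir-rgc"`, `"ftir-enzyme"`.
#' @param fwhm band width override (nm or 1/cm).
#' @return Named list of [species_spectrum()] objects.
#' @export
default_species <- function(preset = c("uvvis-rgc", "ftir-rgc", "ftir-enzyme"),
                            fwhm = NULL) {
  if (!is.character(preset) || !preset[1L] %in%
      c("uvvis-rgc", "ftir-rgc", "ftir-enzyme")) {
    stop("unknown preset '", preset[1L],
         "'; available presets: uvvis-rgc, ftir-rgc, ftir-enzyme",
         call. = FALSE)
  }
  preset <- match.arg(preset)
  if (preset == "uvvis-rgc") {
    w <- if (is.null(fwhm)) 40 else fwhm
    bleach <- spectral_band(545, -1, w)
    return(list(
      K = species_spectrum("K", list(spectral_band(560, 1, w), bleach), "uvvis"),
      L = species_spectrum("L", list(spectral_band(450, 1, w), bleach), "uvvis"),
      M = species_spectrum("M", list(spectral_band(350, 1, w), bleach), "uvvis")))
  }
  w <- if (is.null(fwhm)) 8 else fwhm
  if (preset == "ftir-rgc") {
    fp <- list(spectral_band(1220, -0.5, w), spectral_band(1198, -0.5, w))
    return(list(
      K = species_spectrum("K", c(list(spectral_band(1535, 0.3, w)), fp), "ftir"),
      L = species_spectrum("L", c(list(spectral_band(1647, 1, w),
                                       spectral_band(1665, -0.7, w)), fp), "ftir"),
      M = species_spectrum("M", c(list(spectral_band(1630, 1, w),
                                       spectral_band(1643, -0.7, w)), fp), "ftir")))
  }
  # ftir-enzyme
  list(
    cGMP    = species_spectrum("cGMP", list(spectral_band(1087, 1, w),
                                            spectral_band(1068, 0.7, w)), "ftir"),
    GTP     = species_spectrum("GTP", list(spectral_band(1122, 0.8, w),
                                           spectral_band(923, 0.3, w)), "ftir"),
    NPE     = species_spectrum("NPE", list(spectral_band(1527, -1, w),
                                           spectral_band(1347, -0.8, w)), "ftir"),
    NAP     = species_spectrum("NAP", list(spectral_band(1686, 1, w),
                                           spectral_band(1267, 0.5, w)), "ftir"),
    binding = species_spectrum("binding", list(spectral_band(1070, 0.5, w),
                                               spectral_band(1117, -0.5, w)), "ftir"),
    M       = species_spectrum("M", list(spectral_band(1630, 1, w)), "ftir"))
}
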