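#' Baseline specification
#'
#' Describes how to estimate the signal-free baseline of a spectrum:
#' a straight line (least squares over the anchor positions, at least 2
#' anchors) or a smoothing spline through the anchors (at least 4).
#'
#' @param mode `"linear"` or `"spline"`.
#' @param anchor_points spectral-axis positions assumed signal-free.
#' @param spline_smoothing non-negative smoothing parameter (`spar` of
#'   [stats::smooth.spline()]); `NULL` lets the spline choose.
#' @return An object of class `baseline_spec`.
#' @export
baseline_spec <- function(mode = c("linear", "spline"), anchor_points,
                          spline_smoothing = NULL) {
  mode <- match.arg(mode)
  anchor_points <- sort(as.numeric(anchor_points))
  need <- if (mode == "linear") 2L else 4L
  if (length(anchor_points) < need) {
    stop(sprintf("%s baseline needs >= %d anchor points (got %d)",
                 mode, need, length(anchor_points)), call. = FALSE)
  }
  if (!is.null(spline_smoothing)) {
    stopifnot_scalar_num(spline_smoothing, "spline_smoothing", lower = 0)
  }
  structure(list(mode = mode, anchor_points = anchor_points,
                 spline_smoothing = spline_smoothing),
            class = "baseline_spec")
}

#' Baseline-correct a spectrum
#'
#' Fits the baseline model over the anchor samples (nearest axis samples to
#' the anchor positions) and subtracts it from the whole spectrum. The
#' operation is idempotent: correcting an already corrected spectrum changes
#' nothing beyond the fit residual.
#'
#' @param values spectrum vector, or a matrix (rows = spectra).
#' @param axis spectral axis matching `values`.
#' @param spec a [baseline_spec()].
#' @return Corrected vector or matrix, same shape as `values`, with the
#'   fitted baseline in attribute `"baseline"`.
#' @export
correct_baseline <- function(values, axis, spec) {
  stopifnot(inherits(spec, "baseline_spec"))
  if (is.matrix(values)) {
    out <- t(apply(values, 1L, correct_baseline, axis = axis, spec = spec))
    dimnames(out) <- dimnames(values)
    return(out)
  }
  if (length(values) != length(axis)) {
    stop("'values' and 'axis' lengths differ", call. = FALSE)
  }
  idx <- vapply(spec$anchor_points, function(p) snap_to_axis(axis, p, "anchor"),
                integer(1))
  x <- axis[idx]; y <- values[idx]
  baseline <- if (spec$mode == "linear") {
    fit <- stats::lm.fit(cbind(1, x), y)
    fit$coefficients[1L] + fit$coefficients[2L] * axis
  } else {
    sp <- if (is.null(spec$spline_smoothing)) {
      stats::smooth.spline(x, y)
    } else {
      stats::smooth.spline(x, y, spar = spec$spline_smoothing)
    }
    stats::predict(sp, axis)$y
  }
  out <- values - baseline
  attr(out, "baseline") <- baseline
  out
}

#' N-point moving-average smoothing
#'
#' Centered moving average of width `window`; endpoints use shrinking
#' windows so the length is preserved. Even windows are accepted, with the
#' extra point taken on the trailing side. Smoothing never increases the
#' maximum absolute value of a trace (every output is a mean of inputs).
#'
#' @param values numeric vector.
#' @param window integer window size >= 1, at most `length(values)`.
#' @return Smoothed vector, same length.
#' @export
smooth_trace <- function(values, window) {
  n <- length(values)
  window <- as.integer(window)
  if (window < 1L) stop("'window' must be >= 1", call. = FALSE)
  if (window > n) stop("'window' exceeds trace length", call. = FALSE)
  if (window == 1L) return(values)
  before <- (window - 1L) %/% 2L           # even windows: extra point trails
  after <- window - 1L - before
  cs <- cumsum(c(0, values))
  lo <- pmax(seq_len(n) - before, 1L)
  hi <- pmin(seq_len(n) + after, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Scale spectra on the retinal fingerprint bands
#'
#' Multiplies each spectrum so that its mean absolute amplitude at the two
#' fingerprint band positions (nearest axis samples; defaults 1220 and
#' 1198 1/cm) equals that of the first (reference) spectrum.
#'
#' @param spectra matrix (rows = spectra) or list of equal-length vectors.
#' @param axis spectral axis.
#' @param band_a,band_b fingerprint band positions (1/cm).
#' @return List with `spectra` (same container type as the input, scaled)
#'   and `factors` (numeric, reference first, equal to 1 there).
#' @export
scale_on_fingerprint <- function(spectra, axis, band_a = 1220, band_b = 1198) {
  as_list <- !is.matrix(spectra)
  mat <- if (as_list) do.call(rbind, spectra) else spectra
  ia <- snap_to_axis(axis, band_a, "band_a")
  ib <- snap_to_axis(axis, band_b, "band_b")
  stat <- (abs(mat[, ia]) + abs(mat[, ib])) / 2
  if (any(stat == 0)) {
    stop("zero amplitude at both fingerprint bands in spectrum ",
         which(stat == 0)[1L], "; cannot scale", call. = FALSE)
  }
  factors <- stat[1L] / stat
  scaled <- mat * factors
  if (as_list) scaled <- lapply(seq_len(nrow(scaled)), function(i) scaled[i, ])
  list(spectra = scaled, factors = unname(factors))
}

#' Dark-activity correction of a kinetic trace
#'
#' Fits a least-squares line over a pre-event window (constant-slope dark
#' activity) and subtracts its extrapolation from the whole trace.
#'
#' @param times,values the trace; equal lengths.
#' @param pre_window numeric length-2 interval `(t0, t1)` preceding the
#'   event of interest; must contain at least 3 samples.
#' @return List with `values` (corrected trace), `slope` (removed slope,
#'   signal/s) and `intercept`.
#' @export
dark_activity_correct <- function(times, values, pre_window) {
  stopifnot(length(times) == length(values), length(pre_window) == 2L)
  sel <- times >= pre_window[1L] & times <= pre_window[2L]
  if (sum(sel) < 3L) {
    stop(sprintf("pre_window [%g, %g] contains %d points; need >= 3",
                 pre_window[1L], pre_window[2L], sum(sel)), call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, times[sel]), values[sel])
  b <- fit$coefficients
  list(values = values - (b[1L] + b[2L] * times),
       slope = unname(b[2L]), intercept = unname(b[1L]))
}
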