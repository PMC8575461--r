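#' Marker-band reference table
#'
#' The published marker-band positions used throughout the analyses:
#' amide-I photocycle markers, caged-nucleotide photolysis bands, substrate
#' and product phosphate vibrations. Signs follow the difference-spectrum
#' convention (positive = gain, negative = bleach).
#'
#' @return A data.frame with columns `position` (1/cm), `sign` (`"+"` or
#'   `"-"`), `assignment`, `context`.
#' @export
marker_band_table <- function() {
  tab <- read.csv(system.file("extdata", "marker_bands.csv",
                              package = "rhodokin"),
                  colClasses = c("numeric", "character", "character",
                                 "character"))
  stopifnot(!anyDuplicated(tab$position), all(tab$sign %in% c("+", "-")))
  tab
}

#' Extract a marker-band kinetic trace
#'
#' The trace at a stated band position: values averaged over `window` axis
#' samples centered on the axis sample nearest to `position` (positions
#' snap rather than interpolate -- FTIR axes are dense).
#'
#' @param dataset a [spectral_dataset()].
#' @param position band position (nm or 1/cm) within the axis range.
#' @param window odd number of axis samples to average (default 1).
#' @return An object of class `marker_trace`: `position` (snapped),
#'   `requested`, `snap_distance`, `times`, `values`, `window`,
#'   `corrected` flag.
#' @export
extract_trace <- function(dataset, position, window = 1L) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  axis <- dataset$axis
  j <- snap_to_axis(axis, position)
  half <- (as.integer(window) - 1L) %/% 2L
  cols <- max(1L, j - half):min(length(axis), j + half)
  vals <- rowMeans(dataset$values[, cols, drop = FALSE])
  structure(
    list(position = axis[j], requested = position,
         snap_distance = abs(axis[j] - position),
         times = dataset$times, values = vals,
         window = as.integer(window), corrected = FALSE),
    class = "marker_trace")
}

#' @export
print.marker_trace <- function(x, ...) {
  cat(sprintf("marker_trace at %g (requested %g, snap %g), %d points%s\n",
              x$position, x$requested, x$snap_distance, length(x$times),
              if (x$corrected) ", dark-activity corrected" else ""))
  invisible(x)
}

#' Detect signed peaks in a spectrum
#'
#' Local extrema of the requested sign with topographic prominence at or
#' above a threshold. Prominence of a peak is its height above the higher
#' of the two bounding valleys (walking outward until a higher sample or
#' the spectrum edge). Detection on the negated spectrum with flipped sign
#' yields identical positions.
#'
#' @param values spectrum vector.
#' @param axis spectral axis.
#' @param sign `"positive"` or `"negative"`.
#' @param min_prominence prominence threshold; default 3 times the robust
#'   noise estimate (median absolute deviation) of the spectrum.
#' @return data.frame with columns `position`, `value`, `prominence`,
#'   sorted by decreasing prominence. May have zero rows.
#' @export
detect_signed_peaks <- function(values, axis, sign = c("positive", "negative"),
                                min_prominence = NULL) {
  sign <- match.arg(sign)
  if (is.unsorted(axis) && is.unsorted(rev(axis))) {
    stop("'axis' must be monotone", call. = FALSE)
  }
  x <- if (sign == "negative") -values else values
  if (is.null(min_prominence)) min_prominence <- 3 * stats::mad(values)
  n <- length(x)
  if (n < 3L) return(data.frame(position = numeric(0), value = numeric(0),
                                prominence = numeric(0)))
  is_peak <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n],
               FALSE) & x > 0
  idx <- which(is_peak)
  prom <- vapply(idx, function(i) {
    left_min <- x[i]
    j <- i
    while (j > 1L && x[j - 1L] <= x[i]) {
      j <- j - 1L
      left_min <- min(left_min, x[j])
    }
    if (j == 1L) left_min <- min(left_min, x[1L])
    right_min <- x[i]
    j <- i
    while (j < n && x[j + 1L] <= x[i]) {
      j <- j + 1L
      right_min <- min(right_min, x[j])
    }
    # edge-bounded sides count their full drop
    x[i] - max(left_min, right_min)
  }, numeric(1))
  keep <- prom >= min_prominence
  out <- data.frame(position = axis[idx][keep],
                    value = values[idx][keep],
                    prominence = prom[keep])
  out[order(-out$prominence), , drop = FALSE]
}

#' First time index at which a trace has reached steady state
#'
#' The first index after which the smoothed trace's relative slope
#' (|d value / dt| divided by the maximum absolute trace value) stays below
#' `tolerance` for the remainder of the window. For a saturating
#' exponential `1 - exp(-t/tau)` with tolerance `f / tau` this occurs at
#' `t = tau * log(1 / f)`.
#'
#' @param trace a [extract_trace()] result, or a list with `times` and
#'   `values`.
#' @param tolerance relative-slope threshold in 1/s.
#' @param window optional restriction `(t0, t1)`, e.g. the continuous-
#'   illumination segment; default the whole trace.
#' @param smooth_window smoothing applied before differentiation
#'   (default 5 points).
#' @return List with `index` (integer, 1-based, into the trace times; `NA`
#'   when never reached), `time` (s or `NA`) and `reached` (logical).
#' @export
steady_state_index <- function(trace, tolerance, window = NULL,
                               smooth_window = 5L) {
  times <- trace$times
  values <- trace$values
  sel <- if (is.null(window)) rep(TRUE, length(times)) else {
    times >= window[1L] & times <= window[2L]
  }
  if (sum(sel) < 2L) {
    return(list(index = NA_integer_, time = NA_real_, reached = FALSE))
  }
  t_w <- times[sel]
  v_w <- smooth_trace(values[sel], min(smooth_window, sum(sel)))
  scale <- max(abs(v_w))
  if (scale == 0) {  # identically zero trace is flat from the start
    return(list(index = which(sel)[1L], time = t_w[1L], reached = TRUE))
  }
  slopes <- abs(diff(v_w) / diff(t_w)) / scale
  ok <- c(slopes < tolerance, TRUE)  # slope after last sample undefined
  stays <- rev(cumprod(rev(ok))) > 0
  if (!any(stays)) {
    return(list(index = NA_integer_, time = NA_real_, reached = FALSE))
  }
  first <- which(stays)[1L]
  list(index = which(sel)[first], time = t_w[first], reached = TRUE)
}

#' Onset-similarity of two marker traces
#'
#' Quantifies how closely two marker-band kinetics track each other at
#' illumination onset (e.g. the M-state 1630(+) and product 1087(+)
#' bands). Both traces are dark-activity corrected over a pre-onset
#' window, smoothed (default 8 points), restricted to the onset window and
#' min-max normalized; the report contains the normalized RMS difference
#' (symmetric in the two traces) and the integer-sample lag maximizing the
#' cross-correlation (positive lag: `b` is delayed relative to `a`).
#'
#' @param trace_a,trace_b [extract_trace()] results sharing a time grid
#'   over the onset window.
#' @param onset_window numeric `(t0, t1)` interval around illumination
#'   onset.
#' @param pre_window dark-activity window; defaults to everything before
#'   the onset window (must hold >= 3 points).
#' @param smooth_window smoothing width in points (default 8).
#' @param max_lag maximum lag searched, in samples (default a quarter of
#'   the window).
#' @return List with `rms` (normalized RMS difference), `lag` (samples),
#'   `lag_s` (seconds), `n` (points compared).
#' @export
onset_similarity <- function(trace_a, trace_b, onset_window,
                             pre_window = NULL, smooth_window = 8L,
                             max_lag = NULL) {
  ta <- trace_a$times; tb <- trace_b$times
  sel_a <- ta >= onset_window[1L] & ta <= onset_window[2L]
  sel_b <- tb >= onset_window[1L] & tb <= onset_window[2L]
  if (!any(sel_a) || !any(sel_b)) {
    stop("onset window does not overlap both traces", call. = FALSE)
  }
  if (sum(sel_a) != sum(sel_b) ||
      max(abs(ta[sel_a] - tb[sel_b])) > 1e-9) {
    stop("traces must share a time grid over the onset window", call. = FALSE)
  }
  if (is.null(pre_window)) pre_window <- c(min(ta), onset_window[1L])
  prep <- function(times, values, sel) {
    corr <- dark_activity_correct(times, values, pre_window)$values
    sm <- smooth_trace(corr, min(smooth_window, length(corr)))[sel]
    rng <- range(sm)
    if (diff(rng) == 0) return(sm * 0)
    (sm - rng[1L]) / diff(rng)
  }
  a <- prep(ta, trace_a$values, sel_a)
  b <- prep(tb, trace_b$values, sel_b)
  n <- length(a)
  rms <- sqrt(mean((a - b)^2))
  if (is.null(max_lag)) max_lag <- max(1L, n %/% 4L)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      ai <- a[seq_len(n - l)]; bi <- b[seq_len(n - l) + l]
    } else {
      ai <- a[seq_len(n + l) - l]; bi <- b[seq_len(n + l)]
    }
    if (stats::sd(ai) == 0 || stats::sd(bi) == 0) return(-Inf)
    stats::cor(ai, bi)
  }, numeric(1))
  lag <- lags[which.max(cc)]
  dt <- stats::median(diff(ta[sel_a]))
  list(rms = rms, lag = lag, lag_s = lag * dt, n = n)
}
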