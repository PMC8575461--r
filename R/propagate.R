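#' Propagate photocycle populations under an illumination protocol
#'
#' Solves dp/dt = A(t) p piecewise, using for each protocol segment the rate
#' matrix appropriate to its mode (`cw` switches the D -> K excitation on;
#' `dark` and `uv` leave it off). Flash segments apply the instantaneous
#' fractional D -> K transfer. Within a segment the propagator is the matrix
#' exponential evaluated through the eigendecomposition of the generator;
#' when the eigenvector basis is ill-conditioned (near-degenerate rates) the
#' solver falls back to adaptive ODE integration via \pkg{deSolve}.
#'
#' @param scheme a [kinetic_scheme()].
#' @param protocol an [illumination_protocol()].
#' @param times numeric vector of output times (s), non-decreasing, within
#'   the protocol span. A grid crossing segment boundaries is split
#'   internally.
#' @param init initial state fractions (D, K, L, M) at `min(times)`;
#'   must sum to 1.
#' @param method `"eigen"` (matrix exponential, with automatic fallback) or
#'   `"ode"` (force adaptive integration; used as the independent oracle in
#'   the test-suite).
#' @return An object of class `population_trajectory`: list with `times`
#'   and `populations` (matrix `n_times` x 4, columns D, K, L, M; rows sum
#'   to 1).
#' @export
propagate <- function(scheme, protocol, times,
                      init = c(D = 1, K = 0, L = 0, M = 0),
                      method = c("eigen", "ode")) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(protocol, "illumination_protocol"))
  method <- match.arg(method)
  if (is.unsorted(times)) stop("'times' must be non-decreasing", call. = FALSE)
  if (abs(sum(init) - 1) > 1e-8) {
    stop("'init' state fractions must sum to 1", call. = FALSE)
  }
  if (length(init) != 4L) stop("'init' must have 4 entries (D, K, L, M)", call. = FALSE)

  seg <- protocol$segments
  timed <- seg[seg$duration > 0, , drop = FALSE]
  flashes <- seg$start[seg$mode == "flash"]
  span <- protocol_span(protocol)
  if (min(times) < span[1] - 1e-12 || max(times) > span[2] + 1e-9) {
    stop("'times' must lie within the protocol span", call. = FALSE)
  }
  # the state clock starts at the protocol start, so events (flashes,
  # illumination switches) before the first output sample still act
  t0 <- min(span[1], times[1L])

  # event times: segment boundaries and flashes inside (t0, max(times))
  bounds <- sort(unique(c(timed$start, timed$start + timed$duration, flashes)))
  bounds <- bounds[bounds > t0 + 1e-15 & bounds < max(times) - 1e-15]
  breaks <- c(t0, bounds, max(times))

  light_at <- function(t) {
    # mode of the timed segment covering time t (midpoint query)
    hit <- timed$start <= t & t < timed$start + timed$duration
    if (!any(hit)) return(FALSE)
    timed$mode[which(hit)[1L]] == "cw"
  }

  p <- as.numeric(init)
  out <- matrix(NA_real_, length(times), 4L,
                dimnames = list(NULL, scheme$state_names))
  # flashes exactly at t0 fire before the first interval
  for (tf in flashes[abs(flashes - t0) <= 1e-15]) {
    p <- apply_flash(p, protocol$flash_conversion)
  }
  done <- times <= t0 + 1e-15
  if (any(done)) out[done, ] <- matrix(p, sum(done), 4L, byrow = TRUE)

  for (i in seq_len(length(breaks) - 1L)) {
    a <- breaks[i]; b <- breaks[i + 1L]
    for (tf in flashes[abs(flashes - a) <= 1e-15 & a > t0 + 1e-15]) {
      p <- apply_flash(p, protocol$flash_conversion)
    }
    A <- rate_matrix(scheme, light_on = light_at((a + b) / 2))
    sel <- which(times > a + 1e-15 & times <= b + 1e-15)
    dts <- unique(c(times[sel] - a, b - a))
    vals <- propagate_interval(A, p, dts, method = method)
    if (length(sel)) {
      idx <- match(times[sel] - a, dts)
      out[sel, ] <- t(vals[, idx, drop = FALSE])
    }
    p <- vals[, match(b - a, dts)]
  }

  # guard round-off: renormalize rows to unit sum, clip sub-epsilon dips
  out[out < 0 & out > -1e-12] <- 0
  out <- out / rowSums(out)
  structure(list(times = times, populations = out),
            class = "population_trajectory")
}

apply_flash <- function(p, conversion) {
  moved <- conversion * p[1L]
  p[1L] <- p[1L] - moved
  p[2L] <- p[2L] + moved
  p
}

# Propagate p0 across time offsets dts (>0) under constant generator A.
# Returns a 4 x length(dts) matrix.
propagate_interval <- function(A, p0, dts, method = "eigen") {
  if (all(A == 0)) return(matrix(p0, 4L, length(dts)))
  if (method == "eigen") {
    e <- eigen(A)
    sv <- svd(e$vectors, nu = 0, nv = 0)$d
    if (min(sv) > 1e-9 * max(sv)) {
      c0 <- solve(e$vectors, p0)
      out <- vapply(dts, function(dt) {
        Re(e$vectors %*% (c0 * exp(e$values * dt)))
      }, numeric(4L))
      return(matrix(out, 4L))
    }
    # near-defective generator (repeated rates): fall through to ODE
  }
  ts <- c(0, dts)
  o <- order(ts)
  sol <- deSolve::ode(y = p0, times = ts[o],
                      func = function(t, y, parms) list(as.numeric(A %*% y)),
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  vals <- t(sol[, -1L, drop = FALSE])
  vals[, match(seq_along(ts), o), drop = FALSE][, -1L, drop = FALSE]
}

#' @export
print.population_trajectory <- function(x, ...) {
  cat(sprintf("Population trajectory: %d time points, states %s\n",
              length(x$times), paste(colnames(x$populations), collapse = ", ")))
  invisible(x)
}

#' Export a population trajectory as a data.frame
#'
#' Column 1 is time in seconds, one column per state.
#'
#' @param x a `population_trajectory`.
#' @param ... unused.
#' @return A data.frame with columns `time_s`, `D`, `K`, `L`, `M`.
#' @export
as.data.frame.population_trajectory <- function(x, ...) {
  data.frame(time_s = x$times, x$populations, check.names = FALSE)
}

#' Write / read a trajectory as delimited text
#'
#' @param trajectory a `population_trajectory`.
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a data.frame.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  utils::write.table(format(df, digits = 17, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}
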