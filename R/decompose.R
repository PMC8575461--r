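#' Singular value decomposition of a spectral dataset
#'
#' Standard SVD of the delta-absorbance matrix with components ordered by
#' singular value. Signs are fixed deterministically: each spectral
#' component's largest-magnitude element is made positive. The full-rank
#' reconstruction equals the input to machine precision.
#'
#' @param dataset a [spectral_dataset()] or a plain numeric matrix
#'   (times x channels).
#' @param ... passed to [select_rank()].
#' @return An object of class `svd_result`: `singular_values` (descending),
#'   `temporal_components` (times x k), `spectral_components`
#'   (channels x k), `selected_rank`, plus the `times` and `axis` when a
#'   dataset was supplied.
#' @export
svd_decompose <- function(dataset, ...) {
  values <- if (inherits(dataset, "spectral_dataset")) dataset$values else as.matrix(dataset)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("dataset contains NA or non-finite values", call. = FALSE)
  }
  s <- svd(values)
  for (k in seq_along(s$d)) {
    j <- which.max(abs(s$v[, k]))
    if (s$v[j, k] < 0) {
      s$v[, k] <- -s$v[, k]
      s$u[, k] <- -s$u[, k]
    }
  }
  res <- structure(
    list(singular_values = s$d,
         temporal_components = s$u,
         spectral_components = s$v,
         selected_rank = NA_integer_,
         times = if (inherits(dataset, "spectral_dataset")) dataset$times,
         axis = if (inherits(dataset, "spectral_dataset")) dataset$axis),
    class = "svd_result")
  res$selected_rank <- select_rank(res, ...)
  res
}

#' Select the number of significant SVD components
#'
#' A component counts as signal when it passes both criteria: its singular
#' value is at least `sv_threshold` times the largest one, and its temporal
#' vector is autocorrelated (|lag-1 autocorrelation| >= `ac_threshold`) --
#' noise components are serially uncorrelated. The selected rank is the
#' length of the leading run of significant components, so a pure-noise
#' matrix yields rank 0.
#'
#' @param svd an `svd_result` from [svd_decompose()].
#' @param noise_sigma optional known noise standard deviation; when given,
#'   components whose singular value is below the expected largest noise
#'   singular value `noise_sigma * (sqrt(n) + sqrt(m))` are also rejected.
#' @param sv_threshold relative singular-value threshold (default 1e-2).
#' @param ac_threshold lag-1 autocorrelation threshold (default 0.5).
#' @return Integer rank.
#' @export
select_rank <- function(svd, noise_sigma = NULL,
                        sv_threshold = 1e-2, ac_threshold = 0.5) {
  d <- svd$singular_values
  if (length(d) == 0L || d[1L] == 0) return(0L)
  n <- nrow(svd$temporal_components)
  m <- nrow(svd$spectral_components)
  floor_sv <- if (is.null(noise_sigma)) 0 else noise_sigma * (sqrt(n) + sqrt(m))
  sig <- vapply(seq_along(d), function(i) {
    d[i] / d[1L] >= sv_threshold &&
      d[i] > floor_sv &&
      abs(lag1_autocor(svd$temporal_components[, i])) >= ac_threshold
  }, logical(1))
  r <- 0L
  while (r < length(sig) && sig[r + 1L]) r <- r + 1L
  r
}

# Variable-projection residual: amplitudes solved exactly per channel for a
# candidate set of shared time constants.
vp_solve <- function(logtau, times, Y, fit_offset) {
  tau <- exp(logtau)
  X <- exp(-outer(times, 1 / tau))
  if (fit_offset) X <- cbind(X, 1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) return(list(rss = Inf, B = NULL, X = X))
  B <- qr.coef(qrX, Y)
  resid <- Y - X %*% B
  list(rss = sum(resid^2), B = B, X = X)
}

#' Global multi-exponential fit with shared time constants
#'
#' Fits `delta-A(t, x) = sum_i DADS_i(x) exp(-t / tau_i) (+ offset(x))` to
#' all channels simultaneously by variable projection: for each candidate
#' set of shared time constants the channel amplitudes are solved exactly
#' as a linear least-squares problem, and the time constants are optimized
#' over a log-spaced multi-start grid (exponential fitting is multi-modal).
#' By default the fit runs on the rank-truncated temporal SVD components
#' weighted by their singular values rather than on raw channels; the
#' decay-associated difference spectra (DADS) are then rotated back through
#' the spectral components. The residual sum of squares is identical in
#' both bases for rank >= the number of significant components.
#'
#' @param dataset a [spectral_dataset()], numeric matrix, or `svd_result`.
#' @param n_components number of exponentials (>= 1).
#' @param fit_offset fit a constant per-channel offset (non-decaying
#'   photoproduct)? Default `TRUE`.
#' @param seed integer seed for the multi-start jitter.
#' @param n_starts optimizer starts per component count (default 5).
#' @param use_svd fit in the truncated SVD basis (default) or on raw
#'   channels.
#' @param rank SVD truncation rank; default
#'   `max(n_components, selected rank)`.
#' @param times required when `dataset` is a plain matrix.
#' @return An object of class `global_fit`: `time_constants` (s,
#'   ascending), `dads` (components x channels), `offset` (per-channel
#'   constant, or `NULL`), `rss`, `n_starts`, `seed`, `times`, `axis`.
#' @export
global_exponential_fit <- function(dataset, n_components, fit_offset = TRUE,
                                   seed = 1L, n_starts = 5L, use_svd = TRUE,
                                   rank = NULL, times = NULL) {
  stopifnot(n_components >= 1L)
  if (inherits(dataset, "svd_result")) {
    sv <- dataset
    if (is.null(sv$times)) stop("svd_result lacks a time axis", call. = FALSE)
    times <- sv$times
    axis <- sv$axis
    use_svd <- TRUE
  } else if (inherits(dataset, "spectral_dataset")) {
    times <- dataset$times
    axis <- dataset$axis
    sv <- if (use_svd) svd_decompose(dataset)
  } else {
    if (is.null(times)) stop("'times' required for a matrix input", call. = FALSE)
    axis <- seq_len(ncol(as.matrix(dataset)))
    sv <- if (use_svd) svd_decompose(as.matrix(dataset))
  }
  if (length(times) < 2L * n_components + 2L) {
    stop("need at least 2 * n_components + 2 time points", call. = FALSE)
  }

  if (use_svd) {
    r <- if (!is.null(rank)) rank else max(n_components, sv$selected_rank)
    r <- min(r, length(sv$singular_values))
    Y <- sv$temporal_components[, seq_len(r), drop = FALSE] %*%
      diag(sv$singular_values[seq_len(r)], r)
    Vr <- sv$spectral_components[, seq_len(r), drop = FALSE]
  } else {
    Y <- if (inherits(dataset, "spectral_dataset")) dataset$values else as.matrix(dataset)
    Vr <- NULL
  }

  # shift so the clock starts at the first frame; exp(-t/tau) amplitudes
  # are then defined at t[1]
  t0 <- times[1L]
  ts <- times - t0

  span <- max(ts[ts > 0])
  dt <- min(diff(sort(unique(ts))))
  lo <- log(max(dt / 4, span * 1e-8))
  hi <- log(span * 4)
  starts <- list(seq(lo, hi, length.out = n_components + 2L)[seq_len(n_components) + 1L])
  with_seed(seed, {
    for (i in seq_len(max(0L, n_starts - 1L))) {
      starts[[i + 1L]] <- sort(stats::runif(n_components, lo, hi))
    }
  })

  best <- NULL
  for (st in starts) {
    opt <- try(stats::nlminb(st, function(p) vp_solve(p, ts, Y, fit_offset)$rss,
                             lower = lo - 3, upper = hi + 3),
               silent = TRUE)
    if (inherits(opt, "try-error") || !is.finite(opt$objective)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) {
    stop("global exponential fit failed to converge from any start",
         call. = FALSE)
  }
  sol <- vp_solve(best$par, ts, Y, fit_offset)
  ord <- order(exp(best$par))
  tau <- exp(best$par)[ord]
  B <- sol$B
  amp <- B[ord, , drop = FALSE]
  off <- if (fit_offset) B[n_components + 1L, ] else NULL
  if (!is.null(Vr)) {
    dads <- amp %*% t(Vr)
    offset <- if (!is.null(off)) as.numeric(off %*% t(Vr))
  } else {
    dads <- amp
    offset <- if (!is.null(off)) as.numeric(off)
  }
  structure(
    list(time_constants = tau, dads = dads, offset = offset,
         rss = sol$rss, n_starts = length(starts), seed = as.integer(seed),
         fit_offset = fit_offset, times = times, t0 = t0, axis = axis),
    class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat("Global exponential fit:\n  time constants (s):",
      paste(signif(x$time_constants, 4), collapse = ", "),
      sprintf("\n  rss = %.4g (%d starts, seed %d)\n",
              x$rss, x$n_starts, x$seed))
  invisible(x)
}

#' Reconstruct the fitted surface of a global fit
#'
#' @param fit a `global_fit`.
#' @param times time points (defaults to the fitted grid).
#' @return Matrix times x channels.
#' @export
fitted_surface <- function(fit, times = fit$times) {
  ts <- times - fit$t0
  E <- exp(-outer(ts, 1 / fit$time_constants))
  out <- E %*% fit$dads
  if (!is.null(fit$offset)) out <- out + rep(1, length(ts)) %o% fit$offset
  out
}

# Coefficient matrix A (n_exp x n_species) of the sequential cascade
# 1 -> 2 -> ... -> n -> ground with decay rates k (species i decays at
# k[i]), starting in pure species 1: concentrations C = E %*% A with
# E[, j] = exp(-k[j] t). Classic closed-form solution of a linear chain.
bateman_matrix <- function(k) {
  n <- length(k)
  if (any(duplicated(k))) {
    stop("sequential target analysis needs distinct decay rates", call. = FALSE)
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      num <- prod(k[seq_len(i - 1L)])
      den <- prod(k[setdiff(seq_len(i), j)] - k[j])
      A[j, i] <- num / den
    }
  }
  A
}

# Mixing matrix for the two-component branched decay: L (fraction alpha of
# the initial excited population) decays at k_L, a fraction b of it via M;
# M (initial fraction 1 - alpha) decays at k_M.
branched_matrix <- function(kL, kM, alpha, b) {
  g <- b * kL / (kL - kM)
  # columns = species (L, M), rows = exponentials (fast, slow):
  # p_L = alpha e^{-kL t};  p_M = ((1-alpha) + alpha g) e^{-kM t}
  #                               - alpha g e^{-kL t}
  matrix(c(alpha, -alpha * g,
           0,     (1 - alpha) + alpha * g),
         2L, 2L, byrow = TRUE)
}

#' Rotate decay-associated into species-associated difference spectra
#'
#' Target analysis: under an assumed kinetic topology the concentration
#' profiles are fixed linear combinations of the fitted exponentials,
#' `C(t) = E(t) A`, so the species-associated difference spectra follow
#' from the DADS by the exact linear map `SADS = A^-1 DADS`.
#'
#' Topologies:
#' * `"sequential"`: a unidirectional cascade starting in the fastest
#'   species (for the flash-excited photocycle: L -> M -> dark). The map is
#'   fully determined by the fitted time constants.
#' * `"branched"` (two components): the post-illumination decay of an
#'   L/M mixture where L additionally short-circuits back to the dark
#'   state. Two mixing parameters enter -- the initial L fraction `alpha`
#'   and the branch fraction `b = k_LM / (k_LM + k_LD)`. With free spectra
#'   a single dataset cannot identify them from the residuals (rotational
#'   ambiguity); when not supplied they are estimated by minimal spectral
#'   overlap (which pins their identifiable combination) plus an
#'   equal-norm convention between the two species spectra, so fixing them
#'   from independent knowledge is preferred when available. Joint fits
#'   over several protocols ([compare_topologies()]) identify the branch
#'   fraction properly.
#'
#' @param fit a `global_fit`.
#' @param topology `"sequential"` or `"branched"`.
#' @param init_fraction branched only: known initial L fraction in \[0, 1\],
#'   or `NULL` to estimate.
#' @param branch_fraction branched only: known branch fraction in \[0, 1\],
#'   or `NULL` to estimate.
#' @return An object of class `species_fit`: `topology`, `sads`
#'   (species x channels, rownames `L`, `M`, ... fastest first),
#'   `rate_constants`, `branching_fraction`, `init_fraction`, `mixing`
#'   (the matrix A), and the originating `fit`.
#' @export
dads_to_sads <- function(fit, topology = c("sequential", "branched"),
                         init_fraction = NULL, branch_fraction = NULL) {
  stopifnot(inherits(fit, "global_fit"))
  topology <- match.arg(topology)
  tau <- fit$time_constants
  n <- length(tau)
  k <- 1 / tau

  if (topology == "sequential") {
    A <- bateman_matrix(k)
    sads <- solve(A, fit$dads)
    rates <- if (n == 2L) {
      c(k_LM = k[1L], k_LD = 0, k_MD = k[2L])
    } else {
      stats::setNames(k, paste0("k", seq_len(n)))
    }
    bfrac <- if (n == 2L) 1 else NA_real_
    alpha <- 1
  } else {
    if (n != 2L) {
      stop("branched topology is defined for exactly 2 fitted components",
           call. = FALSE)
    }
    if (is.null(init_fraction) || is.null(branch_fraction)) {
      est <- estimate_branched_mixing(fit, init_fraction, branch_fraction)
      init_fraction <- est[["alpha"]]
      branch_fraction <- est[["b"]]
    }
    A <- branched_matrix(k[1L], k[2L], init_fraction, branch_fraction)
    sads <- solve(A, fit$dads)
    rates <- c(k_LM = branch_fraction * k[1L],
               k_LD = (1 - branch_fraction) * k[1L],
               k_MD = k[2L])
    bfrac <- branch_fraction
    alpha <- init_fraction
  }
  rn <- if (n == 2L) c("L", "M") else paste0("S", seq_len(n))
  rownames(sads) <- rn
  structure(
    list(topology = topology, sads = sads, rate_constants = rates,
         branching_fraction = bfrac, init_fraction = alpha,
         mixing = A, fit = fit, axis = fit$axis),
    class = "species_fit")
}

# Estimate (alpha, b) of the branched two-component decay from the DADS.
#
# With freely fitted spectra only the overlap combination
# c = alpha g / (1 - alpha + alpha g), g = b kL / (kL - kM), is identifiable
# from the spectra themselves: SADS_L is proportional to
# DADS_fast + c * DADS_slow and SADS_M to DADS_slow. Step 1 estimates c by
# minimal spectral overlap (the physical species spectra are less mutually
# correlated than their mixtures). Step 2 resolves the remaining scale
# freedom with the equal-norm convention -- the L and M difference spectra
# carry comparable total amplitude, sharing the same dark-state bleach --
# unless the caller fixes alpha or b outright.
estimate_branched_mixing <- function(fit, init_fraction = NULL,
                                     branch_fraction = NULL) {
  k <- 1 / fit$time_constants
  df <- fit$dads[1L, ]
  ds <- fit$dads[2L, ]
  if (sum(ds^2) == 0 || sum(df^2) == 0) {
    stop("degenerate DADS: cannot estimate branched mixing", call. = FALSE)
  }
  overlap <- function(c_) suppressWarnings(stats::cor(df + c_ * ds, ds)^2)
  c_hat <- stats::optimize(overlap, interval = c(-2, 2))$minimum

  g_of_b <- function(b) b * k[1L] / (k[1L] - k[2L])
  if (!is.null(init_fraction)) {
    alpha <- init_fraction
    g <- c_hat * (1 - alpha) / (alpha * (1 - c_hat))
    b <- if (is.null(branch_fraction)) {
      min(max(g * (k[1L] - k[2L]) / k[1L], 0), 1)
    } else branch_fraction
  } else if (!is.null(branch_fraction)) {
    b <- branch_fraction
    g <- g_of_b(b)
    alpha <- min(max(c_hat / (g + c_hat - c_hat * g), 1e-6), 1 - 1e-6)
  } else {
    rho <- sqrt(sum((df + c_hat * ds)^2) / sum(ds^2))
    alpha <- min(max(rho / (1 - c_hat + rho), 1e-6), 1 - 1e-6)
    g <- c_hat * (1 - alpha) / (alpha * (1 - c_hat))
    b <- min(max(g * (k[1L] - k[2L]) / k[1L], 0), 1)
  }
  c(alpha = alpha, b = b)
}

#' Concentration profiles implied by a species fit
#'
#' @param x a `species_fit`.
#' @param times time points (defaults to the fit grid).
#' @return Matrix times x species; `populations %*% sads` reproduces the
#'   decaying part of the fitted surface exactly.
#' @export
species_populations <- function(x, times = x$fit$times) {
  ts <- times - x$fit$t0
  E <- exp(-outer(ts, 1 / x$fit$time_constants))
  C <- E %*% x$mixing
  colnames(C) <- rownames(x$sads)
  C
}
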