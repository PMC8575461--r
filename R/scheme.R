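#' Branched four-state photocycle scheme
#'
#' Represents the first-order kinetic scheme of a microbial rhodopsin
#' photocycle with states D (dark), K, L and M. The scheme is a cycle
#' D -> K -> L -> M -> D with an optional branch L -> D that short-circuits
#' the M state, plus a light-driven excitation D -> K that is active only
#' while actinic light is on. All rate constants are first order, in 1/s;
#' the corresponding time constants are tau = 1/k.
#'
#' Setting `k_LD = 0` gives a strictly sequential photocycle.
#'
#' @param k_KL K -> L decay rate (1/s). The K state is fast and red-shifted;
#'   its decay constant is rarely resolved, so the default is simply "fast".
#' @param k_LM L -> M rate (1/s).
#' @param k_LD L -> D branch rate (1/s); 0 for a sequential scheme.
#' @param k_MD M -> D recovery rate (1/s).
#' @param k_ex photoexcitation rate D -> K (1/s) while actinic light is on.
#' @param temperature_label free-text label, e.g. `"20C"` or `"-10C"`.
#' @return An object of class `kinetic_scheme`.
#' @seealso [scheme_c259s_20C()], [scheme_wt_20C()], [scheme_c259s_m10C()]
#' @export
kinetic_scheme <- function(k_KL = 1e4, k_LM = 0, k_LD = 0, k_MD = 0,
                           k_ex = 0, temperature_label = "") {
  k <- c(k_KL = k_KL, k_LM = k_LM, k_LD = k_LD, k_MD = k_MD, k_ex = k_ex)
  for (nm in names(k)) {
    if (!is.numeric(k[[nm]]) || length(k[[nm]]) != 1L || is.na(k[[nm]])) {
      stop(sprintf("rate '%s' must be a single number", nm), call. = FALSE)
    }
    if (k[[nm]] < 0) {
      stop(sprintf("negative rate constant for edge '%s': %g", nm, k[[nm]]),
           call. = FALSE)
    }
  }
  structure(
    list(state_names = c("D", "K", "L", "M"),
         k = as.list(k[c("k_KL", "k_LM", "k_LD", "k_MD")]),
         k_ex = k_ex,
         temperature_label = temperature_label),
    class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Photocycle scheme (D -> K -> L -> {M -> D | D})",
      if (nzchar(x$temperature_label)) sprintf("[%s]", x$temperature_label),
      "\n")
  k <- unlist(x$k)
  tau <- ifelse(k > 0, 1 / k, Inf)
  for (i in seq_along(k)) {
    cat(sprintf("  %-5s = %10.4g 1/s   (tau = %.4g s)\n",
                names(k)[i], k[i], tau[i]))
  }
  cat(sprintf("  k_ex  = %10.4g 1/s (light-on only)\n", x$k_ex))
  invisible(x)
}

#' Preset photocycle schemes
#'
#' Rate constants for the slow-cycling C259S mutant and the wild-type
#' rhodopsin at 20 degrees C, expressed through the intermediate lifetimes
#' tau_L = 1/k_LM and tau_M = 1/k_MD (C259S: 40 ms and 3.13 s; wild type:
#' 30 ms and 570 ms). Both room-temperature schemes are sequential
#' (`k_LD = 0`). The -10 degrees C preset scales the C259S constants by the
#' observed temperature factors -- L decay slowed 50-fold, M decay 10-fold --
#' and opens the L -> D branch: at low temperature both L decay paths (to M
#' and directly back to D) have comparable rates, so the default branch
#' fraction k_LM/(k_LM + k_LD) is 0.5.
#'
#' @param k_ex photoexcitation rate D -> K (1/s) under continuous light.
#' @param k_KL K -> L rate (1/s); the K decay is not resolved at 20 C.
#' @param branch_fraction fraction of L decaying via M at -10 C, in \[0, 1\].
#' @return A [kinetic_scheme()].
#' @export
scheme_c259s_20C <- function(k_ex = 0, k_KL = 1e4) {
  kinetic_scheme(k_KL = k_KL, k_LM = 1 / 0.040, k_LD = 0, k_MD = 1 / 3.13,
                 k_ex = k_ex, temperature_label = "C259S 20C")
}

#' @rdname scheme_c259s_20C
#' @export
scheme_wt_20C <- function(k_ex = 0, k_KL = 1e4) {
  kinetic_scheme(k_KL = k_KL, k_LM = 1 / 0.030, k_LD = 0, k_MD = 1 / 0.570,
                 k_ex = k_ex, temperature_label = "WT 20C")
}

#' @rdname scheme_c259s_20C
#' @param L_slowdown,M_slowdown temperature factors applied to the total L
#'   decay and the M decay relative to 20 C.
#' @export
scheme_c259s_m10C <- function(k_ex = 0, k_KL = 1e4, branch_fraction = 0.5,
                              L_slowdown = 50, M_slowdown = 10) {
  if (branch_fraction < 0 || branch_fraction > 1) {
    stop("branch_fraction must lie in [0, 1]", call. = FALSE)
  }
  k_L_total <- (1 / 0.040) / L_slowdown
  kinetic_scheme(k_KL = k_KL,
                 k_LM = branch_fraction * k_L_total,
                 k_LD = (1 - branch_fraction) * k_L_total,
                 k_MD = (1 / 3.13) / M_slowdown,
                 k_ex = k_ex, temperature_label = "C259S -10C")
}

#' Rate matrix (generator) of a photocycle scheme
#'
#' Builds the 4x4 first-order rate matrix A such that dp/dt = A p for the
#' state-fraction vector p = (D, K, L, M). Columns sum to zero
#' (probability-conserving generator); off-diagonal entries are
#' non-negative. The D -> K entry equals `k_ex` if and only if
#' `light_on = TRUE`.
#'
#' @param scheme a [kinetic_scheme()].
#' @param light_on logical; is the actinic light on?
#' @return A 4x4 matrix with dimnames `D, K, L, M`.
#' @export
rate_matrix <- function(scheme, light_on = FALSE) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  st <- scheme$state_names
  A <- matrix(0, 4L, 4L, dimnames = list(st, st))
  k <- scheme$k
  if (isTRUE(light_on) && scheme$k_ex > 0) {
    A["K", "D"] <- A["K", "D"] + scheme$k_ex
    A["D", "D"] <- A["D", "D"] - scheme$k_ex
  }
  A["L", "K"] <- A["L", "K"] + k$k_KL
  A["K", "K"] <- A["K", "K"] - k$k_KL
  A["M", "L"] <- A["M", "L"] + k$k_LM
  A["D", "L"] <- A["D", "L"] + k$k_LD
  A["L", "L"] <- A["L", "L"] - (k$k_LM + k$k_LD)
  A["D", "M"] <- A["D", "M"] + k$k_MD
  A["M", "M"] <- A["M", "M"] - k$k_MD
  A
}

#' Eigen-decay time constants of a scheme
#'
#' Reciprocals of the negated non-zero eigenvalues of the rate matrix,
#' sorted ascending (fastest first). For light-driven cycles the
#' eigenvalues may be complex; the decay constant is then taken from the
#' real part. Near-degenerate (repeated) rates are reported with their
#' multiplicity.
#'
#' @inheritParams rate_matrix
#' @param tol relative tolerance below which an eigenvalue counts as zero.
#' @return Numeric vector of decay time constants in seconds, ascending.
#' @export
eigen_time_constants <- function(scheme, light_on = FALSE, tol = 1e-12) {
  A <- rate_matrix(scheme, light_on = light_on)
  ev <- eigen(A, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  nz <- ev[abs(ev) > tol * scale]
  if (length(nz) == 0L) return(numeric(0))
  rates <- -Re(nz)
  if (any(rates <= 0)) {
    # numerically tiny positive real parts can only arise from round-off
    rates <- rates[rates > tol * scale]
  }
  sort(1 / rates)
}

#' Photostationary state under continuous illumination
#'
#' The unique stationary distribution of the light-on rate matrix, i.e. the
#' normalized null-space vector of the generator. With `k_ex = 0` the system
#' is degenerate (everything relaxes to D); the all-dark distribution is
#' returned with a warning and attribute `degenerate = TRUE`.
#'
#' @param scheme a [kinetic_scheme()] with `k_ex > 0` for a non-trivial
#'   stationary mixture.
#' @return Named numeric vector (D, K, L, M) summing to 1.
#' @export
photostationary <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (scheme$k_ex == 0) {
    warning("k_ex = 0: photostationary state is the all-dark distribution",
            call. = FALSE)
    p <- c(D = 1, K = 0, L = 0, M = 0)
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  A <- rate_matrix(scheme, light_on = TRUE)
  s <- svd(A)
  v <- s$v[, ncol(A)]
  if (sum(v) < 0) v <- -v
  v[v < 0 & v > -1e-12] <- 0
  if (any(v < 0)) {
    stop("stationary vector has negative entries; scheme is not a valid closed cycle",
         call. = FALSE)
  }
  p <- v / sum(v)
  names(p) <- scheme$state_names
  p
}
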