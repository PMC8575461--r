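#' Caged-substrate turnover parameters
#'
#' Parameters of the product-formation model for the two-step uncaging
#' experiment: a constant-rate dark activity, a fast burst from substrate
#' pre-bound to the enzyme upon activation, a slower binding-limited
#' steady turnover under illumination, a (possibly different) post-
#' illumination rate, optional hyperbolic product feedback inhibition, and
#' a finite substrate pool enforcing mass balance.
#'
#' @param v_dark dark-activity product rate (signal/s), active before
#'   enzyme light-activation.
#' @param bound_amplitude burst amplitude from pre-bound substrate
#'   (delta-absorbance equivalents); must not exceed `substrate_total`.
#' @param k_burst first-order rate of the burst (1/s).
#' @param v_light binding-limited turnover rate under illumination
#'   (signal/s).
#' @param v_post post-illumination rate (signal/s); these experiments show
#'   continued, slower production after light-off, so it defaults to
#'   `v_dark` but may differ.
#' @param K_inhib product level at which rates are halved (hyperbolic
#'   feedback inhibition `1 / (1 + P / K_inhib)`); `Inf` disables it.
#' @param substrate_total total substrate pool (bound + free), the hard cap
#'   on cumulative product; `Inf` for an effectively unlimited pool.
#' @return An object of class `turnover_params`.
#' @export
turnover_params <- function(v_dark = 0, bound_amplitude = 0, k_burst = 0,
                            v_light = 0, v_post = v_dark, K_inhib = Inf,
                            substrate_total = Inf) {
  for (nm in c("v_dark", "bound_amplitude", "k_burst", "v_light", "v_post")) {
    stopifnot_scalar_num(get(nm), nm, lower = 0)
  }
  if (!(is.infinite(K_inhib) || K_inhib > 0)) {
    stop("'K_inhib' must be positive (or Inf to disable)", call. = FALSE)
  }
  if (bound_amplitude > substrate_total) {
    stop("'bound_amplitude' exceeds 'substrate_total'", call. = FALSE)
  }
  structure(list(v_dark = v_dark, bound_amplitude = bound_amplitude,
                 k_burst = k_burst, v_light = v_light, v_post = v_post,
                 K_inhib = K_inhib, substrate_total = substrate_total),
            class = "turnover_params")
}

# Phase table of an uncaging protocol: rate regime per time interval.
# regimes: "pre" (dark activity), "active" (burst + light-driven turnover),
# "post" (post-activation dark). For a light-gated enzyme the active
# phases are the cw segments after uncaging; a protocol without any cw
# segment after uncaging describes the constitutively active cyclase,
# active from uncaging onward.
turnover_phases <- function(protocol, t_end) {
  seg <- protocol$segments
  uv <- seg[seg$mode == "uv", , drop = FALSE]
  if (nrow(uv) == 0L) {
    stop("protocol contains no uv (uncaging) segment", call. = FALSE)
  }
  t_uv <- min(uv$start)
  cw <- seg[seg$mode == "cw" & seg$start >= t_uv, , drop = FALSE]
  if (nrow(cw) == 0L) {
    act <- data.frame(start = t_uv, end = t_end)
  } else {
    act <- data.frame(start = cw$start, end = cw$start + cw$duration)
  }
  bounds <- sort(unique(c(0, t_uv, act$start, act$end, t_end)))
  bounds <- bounds[bounds <= t_end]
  ph <- data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
  ph$regime <- vapply(seq_len(nrow(ph)), function(i) {
    mid <- (ph$start[i] + ph$end[i]) / 2
    if (any(act$start <= mid & mid < act$end)) return("active")
    if (mid < min(act$start)) "pre" else "post"
  }, character(1))
  attr(ph, "t_uncage") <- t_uv
  ph
}

#' Simulate a caged-substrate product trace
#'
#' Product signal over time under an uncaging protocol. Before uncaging the
#' trace rises linearly with the dark-activity rate; uncaging makes the
#' substrate available without a product step; during active phases the
#' pre-bound substrate converts in a first-order burst on top of the
#' constant light-driven turnover rate; dark phases use the dark rate
#' before activation and the post rate after. With finite `K_inhib` all
#' rates are scaled by `1 / (1 + P / K_inhib)`; the product never exceeds
#' `substrate_total` and never decreases.
#'
#' @param params a [turnover_params()].
#' @param protocol an [illumination_protocol()] with a `uv` segment.
#' @param times output time grid (s), spanning the protocol.
#' @return Numeric product trace aligned with `times`.
#' @export
simulate_turnover <- function(params, protocol, times) {
  stopifnot(inherits(params, "turnover_params"))
  ph <- turnover_phases(protocol, max(times))
  S_tot <- params$substrate_total
  K <- params$K_inhib

  out <- numeric(length(times))
  P <- 0          # cumulative product
  B <- params$bound_amplitude  # remaining pre-bound substrate
  seen_active <- FALSE

  for (i in seq_len(nrow(ph))) {
    a <- ph$start[i]; b <- ph$end[i]
    sel <- which(times > a + 1e-15 & times <= b + 1e-15)
    if (a > max(times)) break
    regime <- ph$regime[i]
    v <- switch(regime,
                pre = params$v_dark,
                active = params$v_light,
                post = params$v_post)
    kb <- if (regime == "active") params$k_burst else 0
    tt <- unique(c(times[sel] - a, b - a))
    tt <- tt[tt > 0]
    if (length(tt) == 0L) tt <- b - a
    if (b - a > 0) {
      res <- integrate_phase(P, B, v, kb, K, S_tot, tt)
      if (length(sel)) out[sel] <- res$P[match(times[sel] - a, tt)]
      P <- res$P[match(b - a, tt)]
      B <- res$B_end
    }
    if (regime == "active") seen_active <- TRUE
  }
  out[times <= ph$start[1L] + 1e-15] <- 0
  pmin(out, S_tot)
}

# One constant-regime phase: dP = f(P) (k_b B + v), dB = -f(P) k_b B with
# f(P) = 1/(1 + P/K), capped at the substrate pool. Closed form when there
# is no inhibition and the cap stays slack; stiff-safe ODE otherwise.
integrate_phase <- function(P0, B0, v, kb, K, S_tot, tt) {
  if (is.finite(S_tot) && P0 >= S_tot * (1 - 1e-12)) {
    # pool exhausted before this phase: product pinned, bound pool frozen
    return(list(P = rep(S_tot, length(tt)), B_end = unname(B0)))
  }
  uncapped_end <- P0 + B0 * (1 - exp(-kb * max(tt))) * (kb > 0) + v * max(tt)
  if (is.infinite(K) && (is.infinite(S_tot) || uncapped_end <= S_tot)) {
    burst <- if (kb > 0) B0 * (1 - exp(-kb * tt)) else 0
    P <- P0 + burst + v * tt
    return(list(P = P, B_end = if (kb > 0) B0 * exp(-kb * max(tt)) else B0))
  }
  rhs <- function(t, y, parms) {
    f <- if (is.infinite(K)) 1 else 1 / (1 + y[1L] / K)
    list(c(f * (kb * y[2L] + v), -f * kb * y[2L]))
  }
  # integration stops at the substrate cap (mass balance); beyond it the
  # product stays at the cap and the bound pool is frozen
  sol <- deSolve::lsodar(y = c(P = unname(P0), B = unname(B0)),
                         times = c(0, tt), func = rhs,
                         parms = NULL, rtol = 1e-9, atol = 1e-12,
                         rootfunc = if (is.finite(S_tot)) {
                           function(t, y, parms) y[1L] - S_tot
                         })
  P <- rep(S_tot, length(tt))  # times beyond a cap-hit stay at the cap
  got <- match(round(sol[, "time"], 12), round(tt, 12))
  keep <- which(!is.na(got))
  P[got[keep]] <- pmin(sol[keep, "P"], S_tot)
  list(P = P, B_end = unname(sol[nrow(sol), "B"]))
}

#' Piecewise constant-slope fit of a kinetic trace
#'
#' Independent least-squares line per phase (no continuity constraint,
#' matching the usual presentation of constant-slope sections under
#' different illumination conditions).
#'
#' @param times,values the trace (or pass a `marker_trace` as `times`).
#' @param breakpoints interior phase boundaries (s), strictly increasing,
#'   inside the trace span; phases are the intervals between consecutive
#'   boundaries including the trace ends.
#' @return An object of class `phase_fit`: data.frame `phases` with
#'   `start`, `end`, `slope`, `slope_se`, `intercept`, `n`, plus total
#'   `rss`.
#' @export
fit_phases <- function(times, values = NULL, breakpoints) {
  if (inherits(times, "marker_trace")) {
    values <- times$values
    times <- times$times
  }
  stopifnot(length(times) == length(values))
  breakpoints <- sort(breakpoints)
  if (any(breakpoints <= min(times)) || any(breakpoints > max(times))) {
    stop("breakpoints must lie strictly inside the trace span", call. = FALSE)
  }
  edges <- unique(c(min(times), breakpoints, max(times)))
  nph <- length(edges) - 1L
  rows <- vector("list", nph)
  rss <- 0
  for (i in seq_len(nph)) {
    sel <- times >= edges[i] & times <= edges[i + 1L]
    if (i < nph) sel <- sel & times < edges[i + 1L]  # half-open interior
    if (sum(sel) < 3L) {
      stop(sprintf("phase %d [%g, %g] has %d points; need >= 3",
                   i, edges[i], edges[i + 1L], sum(sel)), call. = FALSE)
    }
    tt <- times[sel]; vv <- values[sel]
    fit <- stats::lm.fit(cbind(1, tt), vv)
    r2 <- sum(fit$residuals^2)
    se <- sqrt(r2 / (length(tt) - 2L) / sum((tt - mean(tt))^2))
    rows[[i]] <- data.frame(start = edges[i], end = edges[i + 1L],
                            slope = unname(fit$coefficients[2L]),
                            slope_se = se,
                            intercept = unname(fit$coefficients[1L]),
                            n = sum(sel))
    rss <- rss + r2
  }
  structure(list(phases = do.call(rbind, rows), rss = rss,
                 breakpoints = breakpoints),
            class = "phase_fit")
}

#' @export
print.phase_fit <- function(x, ...) {
  cat("Piecewise constant-slope fit (rss =", signif(x$rss, 4), ")\n")
  print(x$phases, row.names = FALSE)
  invisible(x)
}

#' Fit the turnover model to a product trace
#'
#' Nonlinear least squares over the [turnover_params()] (Levenberg-
#' Marquardt via \pkg{minpack.lm}) with non-negativity bounds, multi-start
#' from data-driven heuristics plus seeded jitter. The inhibition constant
#' is fitted only when `with_inhibition = TRUE`; `substrate_total` is a
#' fixed input (the pool size is set by the experiment, and the mass-
#' balance bound is enforced through it).
#'
#' @param times,values the product trace (or a `marker_trace` as `times`).
#' @param protocol the uncaging [illumination_protocol()].
#' @param with_inhibition fit `K_inhib`? Default `FALSE`.
#' @param substrate_total fixed substrate pool (default `Inf`).
#' @param seed integer seed for multi-start jitter.
#' @param n_starts number of optimizer starts (default 4).
#' @return List with `params` (a [turnover_params()]), `rss`, `fitted`,
#'   and `convergence` info from the best start.
#' @export
fit_turnover <- function(times, values = NULL, protocol,
                         with_inhibition = FALSE, substrate_total = Inf,
                         seed = 1L, n_starts = 4L) {
  if (inherits(times, "marker_trace")) {
    values <- times$values
    times <- times$times
  }
  stopifnot(length(times) == length(values))
  ph <- turnover_phases(protocol, max(times))
  t_act <- min(ph$start[ph$regime == "active"])
  span_act <- max(diff(range(times[times >= t_act])), 1)

  # heuristic scales from the trace
  pre <- times < attr(ph, "t_uncage")
  v0 <- if (sum(pre) >= 3L) {
    max(stats::coef(stats::lm(values[pre] ~ times[pre]))[2L], 1e-8)
  } else 1e-8
  amp0 <- max(max(values) - v0 * max(times), 1e-6)

  par_names <- c("v_dark", "bound_amplitude", "k_burst", "v_light", "v_post",
                 if (with_inhibition) "K_inhib")
  base <- log(c(v_dark = v0, bound_amplitude = 0.5 * amp0,
                k_burst = 5 / span_act, v_light = 0.3 * amp0 / span_act,
                v_post = v0,
                if (with_inhibition) c(K_inhib = amp0)))
  mk_params <- function(p) {
    q <- unname(exp(p))
    turnover_params(v_dark = q[1L],
                    bound_amplitude = min(q[2L], substrate_total),
                    k_burst = q[3L], v_light = q[4L], v_post = q[5L],
                    K_inhib = if (with_inhibition) q[6L] else Inf,
                    substrate_total = substrate_total)
  }
  residual <- function(p) {
    sim <- try(simulate_turnover(mk_params(p), protocol, times), silent = TRUE)
    if (inherits(sim, "try-error")) return(rep(1e6, length(values)))
    sim - values
  }

  starts <- list(base)
  with_seed(seed, {
    for (i in seq_len(max(0L, n_starts - 1L))) {
      starts[[i + 1L]] <- base + stats::rnorm(length(base), 0, 1)
    }
  })
  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(st, fn = residual,
                                  lower = base - 20, upper = base + 12,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 200)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.finite(rss) && (is.null(best) || rss < best$rss)) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("turnover fit failed to converge from any start", call. = FALSE)
  }
  params <- mk_params(best$fit$par)
  list(params = params, rss = best$rss,
       fitted = simulate_turnover(params, protocol, times),
       convergence = list(info = best$fit$info,
                          message = best$fit$message,
                          n_starts = length(starts), seed = as.integer(seed)))
}
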