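# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Index of the axis sample nearest to `position`; errors when out of range.
snap_to_axis <- function(axis, position, what = "position") {
  if (position < min(axis) || position > max(axis)) {
    stop(sprintf("%s %g lies outside the spectral axis [%g, %g]",
                 what, position, min(axis), max(axis)), call. = FALSE)
  }
  which.min(abs(axis - position))
}

# Lag-1 autocorrelation of a vector (0 for constant input).
lag1_autocor <- function(x) {
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0) return(0)
  stats::cor(x[-1L], x[-n])
}

stopifnot_scalar_num <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower) {
    stop(sprintf("'%s' must be >= %g (got %g)", name, lower, x), call. = FALSE)
  }
  invisible(x)
}
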