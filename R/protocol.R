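#' Illumination protocol
#'
#' An ordered, non-overlapping sequence of illumination segments. Modes:
#' `dark` (no light), `cw` (continuous actinic light driving D -> K at rate
#' `k_ex`), `flash` (instantaneous transfer of a fraction `flash_conversion`
#' of D to K; duration must be 0), and `uv` (uncaging light for
#' caged-substrate experiments; it photolyses the caged compound but does
#' not excite the rhodopsin).
#'
#' @param segments a data.frame with columns `start` (s), `duration` (s) and
#'   `mode` (one of `"dark"`, `"flash"`, `"cw"`, `"uv"`).
#' @param flash_conversion fraction of D converted to K by one flash, in
#'   \[0, 1\].
#' @return An object of class `illumination_protocol`.
#' @export
illumination_protocol <- function(segments, flash_conversion = 0.3) {
  stopifnot(is.data.frame(segments),
            all(c("start", "duration", "mode") %in% names(segments)))
  segments$mode <- as.character(segments$mode)
  bad <- setdiff(unique(segments$mode), c("dark", "flash", "cw", "uv"))
  if (length(bad)) {
    stop("unknown segment mode(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(segments$duration < 0)) stop("segment durations must be >= 0", call. = FALSE)
  if (any(segments$mode == "flash" & segments$duration != 0)) {
    stop("flash segments must have duration 0 (instantaneous transfer)",
         call. = FALSE)
  }
  if (flash_conversion < 0 || flash_conversion > 1) {
    stop("flash_conversion must lie in [0, 1]", call. = FALSE)
  }
  timed <- segments[segments$duration > 0, , drop = FALSE]
  timed <- timed[order(timed$start), , drop = FALSE]
  if (nrow(timed) > 1L) {
    ends <- timed$start + timed$duration
    if (any(timed$start[-1L] < ends[-nrow(timed)] - 1e-12)) {
      stop("illumination segments overlap", call. = FALSE)
    }
  }
  segments <- segments[order(segments$start, segments$duration), , drop = FALSE]
  rownames(segments) <- NULL
  structure(list(segments = segments, flash_conversion = flash_conversion),
            class = "illumination_protocol")
}

#' @export
print.illumination_protocol <- function(x, ...) {
  cat("Illumination protocol (flash_conversion =", x$flash_conversion, ")\n")
  print(x$segments)
  invisible(x)
}

protocol_span <- function(protocol) {
  seg <- protocol$segments
  c(min(seg$start), max(seg$start + seg$duration))
}

#' Common illumination protocols
#'
#' `protocol_single_turnover()`: one saturating-or-partial flash at t = 0
#' followed by darkness -- each excited molecule runs the photocycle once.
#' `protocol_cw()`: continuous illumination from t = 0 for `t_on` seconds,
#' then darkness until `t_end` (set `t_on = t_end` for illumination
#' throughout). `protocol_rgc_turnover()` and `protocol_gc_turnover()` are
#' the two-step caged-substrate enzyme protocols: 120 s dark, 5 s UV
#' uncaging, then for the light-gated enzyme 85 s dark, 300 s green (cw)
#' illumination and 364 s dark, while the constitutively active cyclase
#' domain is simply monitored for 364 s after photolysis.
#'
#' @param t_end end of the observation window (s).
#' @param t_on duration of the continuous-illumination segment (s).
#' @param flash_conversion fraction of D converted to K by the flash.
#' @return An [illumination_protocol()].
#' @export
protocol_single_turnover <- function(t_end = 20, flash_conversion = 0.3) {
  illumination_protocol(
    data.frame(start = c(0, 0), duration = c(0, t_end),
               mode = c("flash", "dark")),
    flash_conversion = flash_conversion)
}

#' @rdname protocol_single_turnover
#' @export
protocol_cw <- function(t_on, t_end = t_on) {
  stopifnot(t_end >= t_on)
  seg <- data.frame(start = 0, duration = t_on, mode = "cw")
  if (t_end > t_on) {
    seg <- rbind(seg, data.frame(start = t_on, duration = t_end - t_on,
                                 mode = "dark"))
  }
  illumination_protocol(seg, flash_conversion = 0)
}

#' @rdname protocol_single_turnover
#' @export
protocol_rgc_turnover <- function() {
  illumination_protocol(data.frame(
    start    = c(0,   120,  125,  205,  505),
    duration = c(120, 5,    80,   300,  364),
    mode     = c("dark", "uv", "dark", "cw", "dark")),
    flash_conversion = 0)
}

#' @rdname protocol_single_turnover
#' @export
protocol_gc_turnover <- function() {
  illumination_protocol(data.frame(
    start    = c(0,   120, 125),
    duration = c(120, 5,   364),
    mode     = c("dark", "uv", "dark")),
    flash_conversion = 0)
}
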