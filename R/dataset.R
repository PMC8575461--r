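#' Time-resolved spectral dataset
#'
#' A delta-absorbance matrix on a time axis (rows, seconds) by spectral axis
#' (columns, nm or 1/cm), the package's central container for both measured
#' and synthetic data.
#'
#' @param times numeric vector of times (s), non-decreasing.
#' @param axis monotone spectral axis (nm for `"uvvis"`, 1/cm for `"ftir"`).
#' @param values matrix `length(times)` x `length(axis)` of
#'   delta-absorbance; must be finite.
#' @param domain `"uvvis"` or `"ftir"`.
#' @param metadata free-form provenance list (scheme, protocol, seed, or
#'   `"measured"`).
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(times, axis, values,
                             domain = c("uvvis", "ftir"),
                             metadata = list()) {
  domain <- match.arg(domain)
  values <- as.matrix(values)
  if (nrow(values) != length(times) || ncol(values) != length(axis)) {
    stop(sprintf("values is %d x %d but times/axis are %d/%d",
                 nrow(values), ncol(values), length(times), length(axis)),
         call. = FALSE)
  }
  if (is.unsorted(times)) stop("'times' must be non-decreasing", call. = FALSE)
  if (is.unsorted(axis) && is.unsorted(rev(axis))) {
    stop("'axis' must be monotone", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("'values' contains NA or non-finite entries", call. = FALSE)
  }
  structure(list(times = times, axis = axis, values = values,
                 domain = domain, metadata = metadata),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("spectral_dataset [%s]: %d times x %d %s channels, range [%g, %g]\n",
              x$domain, length(x$times), length(x$axis),
              if (x$domain == "uvvis") "wavelength" else "wavenumber",
              min(x$axis), max(x$axis)))
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$values)

axis_tag <- function(domain) {
  if (domain == "uvvis") "wavelength_nm" else "wavenumber_cm-1"
}

#' Write a spectral dataset as delimited text
#'
#' Format: an optional comment line `# axis: wavelength_nm` or
#' `# axis: wavenumber_cm-1` naming the spectral domain, then a
#' tab-delimited table whose cell (1,1) is `time_s`, first row the spectral
#' axis values, first column the times in seconds. The representation
#' round-trips bit-stably (values written with full precision).
#'
#' @param dataset a [spectral_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# axis: ", axis_tag(dataset$domain)), con)
  fmt <- function(x) sprintf("%.17g", x)
  writeLines(paste(c("time_s", fmt(dataset$axis)), collapse = "\t"), con)
  body <- cbind(fmt(dataset$times),
                matrix(fmt(dataset$values), nrow(dataset$values)))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a spectral dataset from delimited text
#'
#' Parses the format written by [write_dataset()]. The spectral domain is
#' taken from the `# axis:` comment or an axis tag embedded in cell (1,1)
#' (`time_s|wavenumber_cm-1`); without a tag it is inferred from the axis
#' range (values above 900 are treated as wavenumbers). Ragged rows and
#' non-monotone axes are reported with their location.
#'
#' @param path input file path.
#' @return A [spectral_dataset()].
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  domain <- NA_character_
  if (length(lines) && startsWith(lines[1L], "#")) {
    tag <- sub("^#\\s*axis:\\s*", "", lines[1L])
    domain <- switch(tag, "wavelength_nm" = "uvvis", "wavenumber_cm-1" = "ftir",
                     NA_character_)
    lines <- lines[-1L]
  }
  if (length(lines) < 2L) stop("dataset file has no data rows", call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != widths[1L])) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged row %d: %d cells where %d expected",
                 bad, widths[bad], widths[1L]), call. = FALSE)
  }
  head_cell <- cells[[1L]][1L]
  if (grepl("\\|", head_cell)) {
    tag <- sub("^.*\\|", "", head_cell)
    domain <- switch(tag, "wavelength_nm" = "uvvis", "wavenumber_cm-1" = "ftir",
                     domain)
  }
  axis <- suppressWarnings(as.numeric(cells[[1L]][-1L]))
  if (anyNA(axis)) {
    stop(sprintf("malformed axis value at header column %d",
                 which(is.na(axis))[1L] + 1L), call. = FALSE)
  }
  if (is.unsorted(axis) && is.unsorted(rev(axis))) {
    stop("spectral axis in header row is not monotone", call. = FALSE)
  }
  body <- cells[-1L]
  num <- lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(body[[i]]))
    if (anyNA(v)) {
      stop(sprintf("malformed number at row %d, column %d",
                   i + 1L, which(is.na(v))[1L]), call. = FALSE)
    }
    v
  })
  mat <- do.call(rbind, num)
  times <- mat[, 1L]
  if (is.unsorted(times)) stop("time column is not non-decreasing", call. = FALSE)
  if (is.na(domain)) domain <- if (min(axis) > 900) "ftir" else "uvvis"
  spectral_dataset(times, axis, mat[, -1L, drop = FALSE], domain = domain,
                   metadata = list(source = path))
}

#' Write / read a single kinetic trace as two-column text
#'
#' @param times,values trace data; equal length.
#' @param path file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` a
#'   data.frame with columns `time_s` and `value`.
#' @export
write_trace <- function(times, values, path) {
  stopifnot(length(times) == length(values))
  utils::write.table(
    data.frame(time_s = sprintf("%.17g", times),
               value = sprintf("%.17g", values)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  utils::read.delim(path)
}
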