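#' Complex-valued fMRI series
#'
#' Container for a 4D (x, y, z, time) voxel grid of complex values, the
#' native representation of reconstructed MR data before the magnitude is
#' taken. Magnitude-only data are represented with zero phase. The container
#' carries the voxel size (mm) and repetition time TR (s), which every
#' downstream stage (design construction, smoothness in mm, spectra in Hz)
#' reads from here rather than taking as separate arguments.
#'
#' @param data 4D array, complex or numeric (coerced to complex).
#' @param voxel_size_mm length-3 positive numeric, voxel edge length per axis.
#' @param tr_s positive scalar, repetition time in seconds.
#' @return An object of class `complex_series`.
#' @export
complex_series <- function(data, voxel_size_mm = c(1, 1, 1), tr_s = 1) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, time)")
  if (is.numeric(data)) storage.mode(data) <- "double"
  if (!is.complex(data)) data <- data + 0i
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            length(tr_s) == 1L, tr_s > 0)
  structure(list(data = data, voxel_size_mm = voxel_size_mm, tr_s = tr_s),
            class = "complex_series")
}

#' Build a complex series from magnitude and phase volumes
#'
#' @param mag 4D non-negative array of magnitudes.
#' @param phase 4D array of phases in radians, or a scalar (default 0).
#' @inheritParams complex_series
#' @return A `complex_series`.
#' @export
series_from_polar <- function(mag, phase = 0, voxel_size_mm = c(1, 1, 1),
                              tr_s = 1) {
  if (length(phase) == 1L) phase <- array(phase, dim(mag))
  stopifnot(identical(dim(mag), dim(phase)))
  complex_series(mag * exp(1i * phase), voxel_size_mm, tr_s)
}

#' @export
print.complex_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<complex_series> %d x %d x %d voxels, %d volumes\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size: %s mm, TR: %g s\n",
              paste(signif(x$voxel_size_mm, 3), collapse = " x "), x$tr_s))
  invisible(x)
}

#' Magnitude of a series
#' @param x a `complex_series` or numeric 4D array.
#' @return 4D numeric array of magnitudes.
#' @export
series_magnitude <- function(x) {
  if (inherits(x, "complex_series")) Mod(x$data) else abs(x)
}

#' Phase of a series
#' @param x a `complex_series`.
#' @return 4D numeric array of phases in radians.
#' @export
series_phase <- function(x) Arg(as_series(x)$data)

# Accept either a complex_series or a bare 4D array (treated as magnitude
# data with unit voxels / TR); internal normalization used by most entry
# points so evaluation code can be fed plain arrays in tests.
as_series <- function(x, voxel_size_mm = c(1, 1, 1), tr_s = 1) {
  if (inherits(x, "complex_series")) return(x)
  complex_series(x, voxel_size_mm, tr_s)
}

n_volumes <- function(x) dim(as_series(x)$data)[4L]

grid_dims <- function(x) dim(as_series(x)$data)[1:3]

# Voxels-by-time matrix view of the data (no copy semantics guaranteed).
series_matrix <- function(x, what = c("complex", "magnitude", "real")) {
  x <- as_series(x)
  what <- match.arg(what)
  d <- dim(x$data)
  m <- matrix(x$data, prod(d[1:3]), d[4])
  switch(what, complex = m, magnitude = Mod(m), real = Re(m))
}

# Rebuild a series like `template` with new data (matrix or array).
series_like <- function(template, data) {
  template <- as_series(template)
  dim(data) <- dim(template$data)
  complex_series(data, template$voxel_size_mm, template$tr_s)
}
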