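#' Time-resolved 3-component velocity field on a regular grid
#'
#' The common currency of the package: MRI phase-contrast velocity data and
#' resampled simulation output are both held as a `velocity_field`. Values
#' are in m/s; component order is fixed to (AP, RL, SI) and the mapping of
#' grid axes to anatomical directions lives in the geometry's `axes`.
#'
#' `NA` values are permitted and mark missing/uncovered voxels (e.g. outside
#' the support of a resampled field); `NaN`/`Inf` are rejected.
#'
#' @param values numeric array `[nx, ny, nz, 3]` (single frame) or
#'   `[nx, ny, nz, 3, nt]` (time-resolved), m/s.
#' @param geometry a [grid_geometry()].
#' @param times numeric vector of frame time stamps in seconds (length nt).
#' @param venc optional velocity-encoding limit, m/s; stored components must
#'   satisfy `|v| <= venc`.
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(values, geometry, times = 0, venc = NULL) {
  stopifnot(inherits(geometry, "grid_geometry"))
  d <- dim(values)
  if (length(d) == 4L) {
    values <- array(values, dim = c(d, 1L))
    d <- dim(values)
  }
  if (length(d) != 5L || d[4] != 3L)
    stop_flow4d("values must be [nx, ny, nz, 3(, nt)]", "flow4d_shape_error")
  if (!all(d[1:3] == geometry$shape))
    stop_flow4d("values dimensions do not match geometry shape", "flow4d_shape_error")
  times <- as.numeric(times)
  if (length(times) != d[5])
    stop_flow4d("length(times) must equal the number of frames", "flow4d_shape_error")
  if (any(is.nan(values)) || any(is.infinite(values)))
    stop_flow4d("velocity values must be finite or NA", "flow4d_value_error")
  if (!is.null(venc)) {
    if (!is_scalar_number(venc) || venc <= 0)
      stop_flow4d("venc must be a positive number (m/s)", "flow4d_parameter_error")
    if (any(abs(values) > venc + 1e-12, na.rm = TRUE))
      stop_flow4d("stored velocity components exceed venc", "flow4d_value_error")
  }
  structure(list(geometry = geometry, values = values, times = times,
                 venc = venc),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat("velocity_field:", paste(x$geometry$shape, collapse = " x "),
      "voxels,", n_frames(x), "frame(s), components (AP, RL, SI) m/s\n")
  invisible(x)
}

#' Number of time frames of a velocity field
#' @param field a [velocity_field()].
#' @export
n_frames <- function(field) dim(field$values)[5]

# [nx,ny,nz,3] array of one frame, with index check
frame_values <- function(field, frame) {
  nt <- n_frames(field)
  if (!is_scalar_number(frame) || frame < 1 || frame > nt || frame != round(frame))
    stop_flow4d(sprintf("frame %s out of range 1..%d", format(frame), nt),
                "flow4d_index_error")
  v <- field$values[, , , , frame, drop = FALSE]
  dim(v) <- dim(field$values)[1:4]  # keep size-1 axes
  v
}

#' Scalar volume with a declared unit
#'
#' @param values numeric 3-D array matching `geometry$shape`.
#' @param geometry a [grid_geometry()].
#' @param unit one of `"m/s"` (speed), `"a.u."` (magnitude),
#'   `"m^2/s^2"` (turbulent kinetic energy k), `"m^2/s^3"` (dissipation
#'   rate epsilon), `"Pa.s"` (viscosity).
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, geometry,
                          unit = c("m/s", "a.u.", "m^2/s^2", "m^2/s^3", "Pa.s")) {
  stopifnot(inherits(geometry, "grid_geometry"))
  unit <- match.arg(unit)
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == geometry$shape))
    stop_flow4d("values dimensions do not match geometry shape", "flow4d_shape_error")
  if (any(is.nan(values)) || any(is.infinite(values)))
    stop_flow4d("scalar values must be finite or NA", "flow4d_value_error")
  structure(list(geometry = geometry, values = values, unit = unit),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("scalar_volume:", paste(x$geometry$shape, collapse = " x "),
      "voxels, unit", x$unit, "\n")
  invisible(x)
}

#' Binary lumen mask on a regular grid
#'
#' @param values logical 3-D array matching `geometry$shape`.
#' @param geometry a [grid_geometry()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == geometry$shape))
    stop_flow4d("mask dimensions do not match geometry shape", "flow4d_shape_error")
  storage.mode(values) <- "logical"
  if (any(is.na(values)))
    stop_flow4d("mask values must be TRUE/FALSE", "flow4d_value_error")
  structure(list(geometry = geometry, values = values),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("binary_mask:", paste(x$geometry$shape, collapse = " x "),
      "voxels,", sum(x$values), "in-mask\n")
  invisible(x)
}
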