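#' Regular grid geometry of a medical volume
#'
#' Describes the sampling lattice shared by velocity fields, scalar volumes
#' and masks: voxels per axis, voxel spacing in millimetres, the world
#' position (mm) of the centre of voxel (1,1,1), and the anatomical
#' direction of each grid axis.
#'
#' Conventions: voxel indices are 1-based (R convention); the world position
#' of voxel (i, j, k) is `origin + (c(i, j, k) - 1) * spacing`; a voxel's
#' value is located at its centre. Axis labels are a permutation of
#' AP (anterior-posterior), RL (right-left) and SI (superior-inferior).
#'
#' @param shape integer 3-vector, voxels per axis (each >= 1).
#' @param spacing numeric 3-vector, voxel spacing in mm (each > 0).
#' @param origin numeric 3-vector, world position (mm) of voxel (1,1,1).
#' @param axes character 3-vector, permutation of `c("AP","RL","SI")`.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(shape, spacing, origin = c(0, 0, 0),
                          axes = c("AP", "RL", "SI")) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop_flow4d("shape must be 3 integers >= 1", "flow4d_parameter_error")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_flow4d("spacing must be 3 positive numbers (mm)", "flow4d_parameter_error")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop_flow4d("origin must be 3 finite numbers (mm)", "flow4d_parameter_error")
  if (length(axes) != 3L || !setequal(axes, c("AP", "RL", "SI")))
    stop_flow4d("axes must be a permutation of AP, RL, SI", "flow4d_parameter_error")
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 axes = as.character(axes)),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat("grid_geometry:", paste(x$shape, collapse = " x "), "voxels,",
      paste(format(x$spacing), collapse = " x "), "mm, origin (",
      paste(format(x$origin), collapse = ", "), ") mm, axes",
      paste(x$axes, collapse = "/"), "\n")
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

#' World coordinates of voxel centres
#'
#' @param geometry a [grid_geometry()].
#' @param index integer matrix (n x 3) of 1-based voxel indices; if missing,
#'   all voxels in grid order (first axis fastest).
#' @return n x 3 matrix of world positions in mm.
#' @export
voxel_centers <- function(geometry, index = NULL) {
  if (is.null(index)) {
    index <- as.matrix(expand.grid(i = seq_len(geometry$shape[1]),
                                   j = seq_len(geometry$shape[2]),
                                   k = seq_len(geometry$shape[3])))
  }
  index <- matrix(as.numeric(index), ncol = 3L)
  sweep(sweep(index - 1, 2, geometry$spacing, "*"), 2, geometry$origin, "+")
}

# world mm -> continuous 0-based voxel index
world_to_index0 <- function(geometry, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  sweep(sweep(pts, 2, geometry$origin, "-"), 2, geometry$spacing, "/")
}

# voxel volume in m^3 (spacing is mm)
voxel_volume_m3 <- function(geometry) prod(geometry$spacing * 1e-3)
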