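#' Per-voxel speed of a velocity frame
#'
#' Euclidean norm of the three velocity components, the "phase velocity
#' image" used to define the lumen boundary at peak systole.
#'
#' @param field a [velocity_field()].
#' @param frame 1-based frame index.
#' @return A [scalar_volume()] in m/s. `NA` components give `NA` speed.
#' @export
speed_volume <- function(field, frame = 1L) {
  stopifnot(inherits(field, "velocity_field"))
  v <- frame_values(field, frame)
  s <- sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2)
  scalar_volume(s, field$geometry, unit = "m/s")
}

#' Coarse lumen segmentation by speed threshold
#'
#' @param speed a [scalar_volume()] in m/s.
#' @param threshold non-negative speed threshold, m/s; voxels with
#'   `speed >= threshold` become mask foreground.
#' @return A [binary_mask()].
#' @export
threshold_segment <- function(speed, threshold) {
  stopifnot(inherits(speed, "scalar_volume"))
  if (!is_scalar_number(threshold) || threshold < 0)
    stop_flow4d("threshold must be a non-negative number (m/s)",
                "flow4d_parameter_error")
  m <- !is.na(speed$values) & speed$values >= threshold
  binary_mask(m, speed$geometry)
}

#' Connected component containing a seed (3D region growing)
#'
#' Keeps only the foreground voxels connected to the seed under the chosen
#' neighbourhood; this is the classic 3D region-growing step applied after
#' coarse thresholding to discard disconnected structures.
#'
#' @param mask a [binary_mask()].
#' @param seed integer 3-vector, 1-based voxel index inside the grid.
#' @param connectivity 6 (face) or 26 (face+edge+corner, default).
#' @return A [binary_mask()]; empty (with a warning) if the seed voxel is
#'   background.
#' @export
region_grow <- function(mask, seed, connectivity = 26L) {
  stopifnot(inherits(mask, "binary_mask"))
  seed <- as.integer(seed)
  sh <- mask$geometry$shape
  if (length(seed) != 3L || any(seed < 1L) || any(seed > sh))
    stop_flow4d("seed voxel outside the grid", "flow4d_index_error")
  offs <- neighbor_offsets(as.integer(connectivity))
  m <- mask$values
  if (!m[seed[1], seed[2], seed[3]]) {
    warning("seed voxel is background; returning an empty mask")
    return(binary_mask(array(FALSE, dim = sh), mask$geometry))
  }
  comp <- array(FALSE, dim = sh)
  comp[seed[1], seed[2], seed[3]] <- TRUE
  frontier <- comp
  repeat {
    grown <- array(FALSE, dim = sh)
    for (r in seq_len(nrow(offs)))
      grown <- grown | shift3(frontier, offs[r, 1], offs[r, 2], offs[r, 3],
                              fill = FALSE)
    frontier <- grown & m & !comp
    if (!any(frontier)) break
    comp <- comp | frontier
  }
  binary_mask(comp, mask$geometry)
}

# foreground voxels with at least one background 6-neighbour
# (voxels beyond the grid edge count as background)
boundary_voxels <- function(m) {
  inner <- m
  for (r in seq_len(6)) {
    o <- neighbor_offsets(6L)[r, ]
    inner <- inner & shift3(m, o[1], o[2], o[3], fill = FALSE)
  }
  m & !inner
}

#' Velocity-guided boundary refinement
#'
#' Automated surrogate for voxel-by-voxel manual boundary correction
#' against the phase velocity images: boundary voxels (foreground voxels
#' with a background 6-neighbour) whose speed is below
#' `boundary_threshold` are removed, and the pass is iterated to a fixed
#' point. The result is always a subset of the input mask.
#'
#' @param mask a [binary_mask()].
#' @param speed a [scalar_volume()] (m/s) on the same grid.
#' @param boundary_threshold speed below which a boundary voxel is culled,
#'   m/s.
#' @return A refined [binary_mask()].
#' @export
refine_boundary <- function(mask, speed, boundary_threshold) {
  stopifnot(inherits(mask, "binary_mask"), inherits(speed, "scalar_volume"))
  if (!same_geometry(mask$geometry, speed$geometry))
    stop_flow4d("mask and speed volumes are on different grids",
                "flow4d_shape_error")
  if (!is_scalar_number(boundary_threshold) || boundary_threshold < 0)
    stop_flow4d("boundary_threshold must be non-negative", "flow4d_parameter_error")
  m <- mask$values
  s <- speed$values
  repeat {
    cull <- boundary_voxels(m) & (is.na(s) | s < boundary_threshold)
    if (!any(cull)) break
    m <- m & !cull
  }
  binary_mask(m, mask$geometry)
}

#' Apply a scripted list of voxel edits to a mask
#'
#' Represents manual segmentation correction as a reproducible artifact: a
#' list of (voxel index, value) pairs instead of an interactive session.
#'
#' @param mask a [binary_mask()].
#' @param edits a data.frame or matrix with columns `i, j, k, value`
#'   (1-based voxel index, logical/0-1 value). Zero rows are allowed.
#' @return The edited [binary_mask()].
#' @export
edit_mask <- function(mask, edits) {
  stopifnot(inherits(mask, "binary_mask"))
  edits <- as.data.frame(edits)
  if (nrow(edits) == 0L) return(mask)
  if (ncol(edits) < 4L)
    stop_flow4d("edits need columns i, j, k, value", "flow4d_parameter_error")
  idx <- as.matrix(edits[, 1:3])
  storage.mode(idx) <- "integer"
  sh <- mask$geometry$shape
  if (any(is.na(idx)) || any(idx < 1L) ||
      any(idx[, 1] > sh[1] | idx[, 2] > sh[2] | idx[, 3] > sh[3]))
    stop_flow4d("edit voxel index outside the grid", "flow4d_index_error")
  m <- mask$values
  m[idx] <- as.logical(edits[[4]])
  binary_mask(m, mask$geometry)
}
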