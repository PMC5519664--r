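# User-facing volume readers/writers dispatching on format.

guess_volume_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         nii = "nifti", nrrd = "nrrd", nhdr = "nrrd", vtk = "vtk",
         stop_flow4d(sprintf("cannot infer volume format of '%s'", path),
                     "flow4d_format_error"))
}

#' Read a 3-component velocity volume
#'
#' Accepts a NIfTI-1 vector volume (`dim = [nx,ny,nz,nt,3]` or
#' `[nx,ny,nz,3]`), a NRRD vector volume (component axis marked
#' `kind: vector`, or any axis of size 3 flanking three space axes), a
#' legacy VTK structured-points file with `VECTORS` point data, or three
#' parallel single-component volumes (pass a character vector of 3 paths,
#' in AP/RL/SI order). Spacing is taken from the file header and converted
#' to mm; velocities are interpreted as m/s.
#'
#' @param path file path, or 3 paths (one per component).
#' @param format `"auto"` (from extension), `"nifti"`, `"nrrd"` or `"vtk"`.
#' @param axes anatomical labels of the grid axes, default
#'   `c("AP","RL","SI")`; also taken as the component order of the stored
#'   vectors.
#' @return A [velocity_field()].
#' @export
read_velocity_volume <- function(path, format = c("auto", "nifti", "nrrd", "vtk"),
                                 axes = c("AP", "RL", "SI")) {
  format <- match.arg(format)
  if (length(path) == 3L) {
    vols <- lapply(path, read_scalar_volume, format = format, axes = axes)
    g <- vols[[1]]$geometry
    for (v in vols[-1]) if (!same_geometry(g, v$geometry))
      stop_flow4d("component volumes are on different grids", "flow4d_shape_error")
    vals <- array(0, dim = c(g$shape, 3L))
    for (d in 1:3) vals[, , , d] <- vols[[d]]$values
    return(velocity_field(vals, g))
  }
  if (!file.exists(path))
    stop_flow4d(sprintf("file '%s' does not exist", path), "flow4d_format_error")
  if (format == "auto") format <- guess_volume_format(path)
  if (format == "nifti") {
    x <- read_nifti_raw(path)
    nd <- length(x$dims)
    if (nd == 4L && x$dims[4] == 3L) {
      vals <- array(x$data, dim = c(x$dims[1:3], 3L, 1L))
      times <- 0
    } else if (nd == 5L && x$dims[5] == 3L) {
      vals <- x$data  # [nx,ny,nz,nt,3] -> [nx,ny,nz,3,nt]
      vals <- aperm(vals, c(1, 2, 3, 5, 4))
      dt <- if (is.finite(x$dt) && x$dt > 0) x$dt else 1
      times <- x$toffset + (seq_len(x$dims[4]) - 1) * dt
    } else {
      stop_flow4d(sprintf("expected 3 velocity components, got dims [%s]",
                          paste(x$dims, collapse = ", ")), "flow4d_shape_error")
    }
    venc <- NULL
    m <- regmatches(x$descrip, regexec("venc=([0-9.eE+-]+)", x$descrip))[[1]]
    if (length(m) == 2L) venc <- as.numeric(m[2])
    g <- grid_geometry(dim(vals)[1:3], x$spacing, x$origin, axes)
    velocity_field(vals, g, times = times, venc = venc)
  } else if (format == "nrrd") {
    x <- read_nrrd_raw(path)
    comp_axis <- which(x$dims == 3L & x$kinds != "space")
    if (length(comp_axis) == 0L) comp_axis <- which(x$dims == 3L)
    if (length(x$dims) != 4L || length(comp_axis) == 0L)
      stop_flow4d(sprintf("expected 3 velocity components, got sizes [%s]",
                          paste(x$dims, collapse = ", ")), "flow4d_shape_error")
    comp_axis <- comp_axis[1]
    perm <- c(setdiff(1:4, comp_axis), comp_axis)
    vals <- aperm(x$data, perm)
    g <- grid_geometry(dim(vals)[1:3], x$spacing, x$origin, axes)
    velocity_field(vals, g)
  } else {
    x <- read_vtk_structured_points(path)
    if (is.null(x$vectors))
      stop_flow4d("VTK file has no vector point data (1 component per voxel?)",
                  "flow4d_shape_error")
    g <- grid_geometry(x$shape, x$spacing, x$origin, axes)
    velocity_field(x$vectors, g)
  }
}

#' Write a velocity field
#'
#' NIfTI-1 keeps all time frames (`dim = [nx,ny,nz,nt,3]`, float64, venc
#' recorded in `descrip`); NRRD and VTK write a single selected frame.
#'
#' @param field a [velocity_field()].
#' @param path output path.
#' @param format `"auto"` (from extension), `"nifti"`, `"nrrd"` or `"vtk"`.
#' @param frame frame to write for single-frame formats (default 1).
#' @export
write_velocity_volume <- function(field, path,
                                  format = c("auto", "nifti", "nrrd", "vtk"),
                                  frame = 1L) {
  stopifnot(inherits(field, "velocity_field"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_volume_format(path)
  g <- field$geometry
  if (format == "nifti") {
    nt <- n_frames(field)
    arr <- aperm(field$values, c(1, 2, 3, 5, 4))  # [nx,ny,nz,nt,3]
    dt <- if (nt > 1) mean(diff(field$times)) else 0
    if (nt > 2 && max(abs(diff(field$times) - dt)) > 1e-9)
      warning("non-uniform frame times stored as a uniform NIfTI time step")
    descrip <- if (!is.null(field$venc)) sprintf("venc=%.17g", field$venc) else ""
    write_nifti_raw(path, c(g$shape, nt, 3L), c(g$spacing, dt), g$origin,
                    arr, intent_code = 1007L, descrip = descrip,
                    toffset = field$times[1])
  } else if (format == "nrrd") {
    vals <- frame_values(field, frame)
    payload <- aperm(vals, c(4, 1, 2, 3))  # component fastest
    write_nrrd_raw(path, c(3L, g$shape), g$spacing, g$origin, payload,
                   kinds = c("vector", "space", "space", "space"))
  } else {
    write_vtk_structured_points(path, g$shape, g$spacing, g$origin,
                                vectors = frame_values(field, frame))
  }
  invisible(path)
}

#' Read a scalar volume (or mask) from NIfTI-1, NRRD or VTK
#'
#' @param path file path.
#' @param format `"auto"`, `"nifti"`, `"nrrd"` or `"vtk"`.
#' @param unit unit tag for the values, see [scalar_volume()].
#' @param axes anatomical axis labels, default `c("AP","RL","SI")`.
#' @return A [scalar_volume()].
#' @export
read_scalar_volume <- function(path, format = c("auto", "nifti", "nrrd", "vtk"),
                               unit = "m/s", axes = c("AP", "RL", "SI")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_flow4d(sprintf("file '%s' does not exist", path), "flow4d_format_error")
  if (format == "auto") format <- guess_volume_format(path)
  if (format == "nifti") {
    x <- read_nifti_raw(path)
    dims <- x$dims[x$dims > 1L]
    if (length(dims) != 3L)
      stop_flow4d("expected a single-component 3-D volume", "flow4d_shape_error")
    g <- grid_geometry(dims, x$spacing, x$origin, axes)
    scalar_volume(array(x$data, dim = dims), g, unit = unit)
  } else if (format == "nrrd") {
    x <- read_nrrd_raw(path)
    if (length(x$dims) != 3L)
      stop_flow4d("expected a single-component 3-D volume", "flow4d_shape_error")
    g <- grid_geometry(x$dims, x$spacing, x$origin, axes)
    scalar_volume(x$data, g, unit = unit)
  } else {
    x <- read_vtk_structured_points(path)
    if (is.null(x$scalars))
      stop_flow4d("VTK file has no scalar point data", "flow4d_shape_error")
    g <- grid_geometry(x$shape, x$spacing, x$origin, axes)
    scalar_volume(x$scalars, g, unit = unit)
  }
}

#' Write a scalar volume or binary mask
#'
#' Masks are written as 0/1 volumes.
#'
#' @param volume a [scalar_volume()] or [binary_mask()].
#' @param path output path.
#' @param format `"auto"`, `"nifti"`, `"nrrd"` or `"vtk"`.
#' @export
write_scalar_volume <- function(volume, path,
                                format = c("auto", "nifti", "nrrd", "vtk")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_volume_format(path)
  if (inherits(volume, "binary_mask")) {
    vals <- array(0, dim = volume$geometry$shape)
    vals[volume$values] <- 1
  } else {
    stopifnot(inherits(volume, "scalar_volume"))
    vals <- volume$values
  }
  g <- volume$geometry
  if (format == "nifti") {
    write_nifti_raw(path, g$shape, g$spacing, g$origin, vals)
  } else if (format == "nrrd") {
    write_nrrd_raw(path, g$shape, g$spacing, g$origin, vals,
                   kinds = c("space", "space", "space"))
  } else {
    write_vtk_structured_points(path, g$shape, g$spacing, g$origin,
                                scalars = vals, name = "scalar")
  }
  invisible(path)
}

#' Read a binary mask (values >= 0.5 become foreground)
#'
#' @inheritParams read_scalar_volume
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, format = c("auto", "nifti", "nrrd", "vtk"),
                      axes = c("AP", "RL", "SI")) {
  v <- read_scalar_volume(path, format, unit = "a.u.", axes = axes)
  binary_mask(!is.na(v$values) & v$values >= 0.5, v$geometry)
}
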