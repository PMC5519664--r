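#' Blood fluid properties
#'
#' @param mu dynamic viscosity, Pa s. Default 0.004 (blood).
#' @param rho density, kg/m^3. Default 1060 (blood; configurable because
#'   mass flows in kg/s scale linearly with it).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(mu = 0.004, rho = 1060) {
  if (!is_scalar_number(mu) || mu <= 0)
    stop_flow4d("mu must be > 0 (Pa s)", "flow4d_parameter_error")
  if (!is_scalar_number(rho) || rho <= 0)
    stop_flow4d("rho must be > 0 (kg/m^3)", "flow4d_parameter_error")
  structure(list(mu = mu, rho = rho), class = "fluid_properties")
}

#' Turbulence closure model for the energy-loss integral
#'
#' `laminar` sets the eddy viscosity to zero; `les_smagorinsky` computes it
#' from the resolved strain rate, `mu_t = (c_s * delta)^2 * sqrt(2 S:S)`;
#' `rng_k_epsilon` evaluates `mu_t = c_mu * rho * k^2 / epsilon` from
#' externally supplied k and epsilon volumes (solving their transport
#' equations is a CFD-solver task, not done here).
#'
#' @param kind one of `"laminar"`, `"les_smagorinsky"`, `"rng_k_epsilon"`.
#' @param c_mu RNG k-epsilon constant, default 0.0845.
#' @param c_s Smagorinsky constant, default 0.1.
#' @param delta local grid size in metres for the LES closure; default
#'   (`NULL`) is the cube root of the voxel volume.
#' @return An object of class `closure_model`.
#' @export
closure_model <- function(kind = c("laminar", "les_smagorinsky", "rng_k_epsilon"),
                          c_mu = 0.0845, c_s = 0.1, delta = NULL) {
  kind <- match.arg(kind)
  if (!is_scalar_number(c_mu) || c_mu <= 0 || !is_scalar_number(c_s) || c_s <= 0)
    stop_flow4d("closure constants must be > 0", "flow4d_parameter_error")
  if (!is.null(delta) && (!is_scalar_number(delta) || delta <= 0))
    stop_flow4d("delta must be > 0 (m)", "flow4d_parameter_error")
  structure(list(kind = kind, c_mu = c_mu, c_s = c_s, delta = delta),
            class = "closure_model")
}

#' Sample velocity a fixed depth inside the wall
#'
#' For each mesh face, interpolates the velocity trilinearly at
#' `face centre - depth * outward normal`, i.e. a point `depth` metres
#' inside the lumen. Faces whose sample point leaves the grid (or lands on
#' missing data) are flagged invalid.
#'
#' @param mesh a [tri_mesh()] lying inside the field's grid.
#' @param field a [velocity_field()].
#' @param frame 1-based frame index.
#' @param depth sampling depth in metres (> 0).
#' @return A list with `velocity` (n_faces x 3 matrix, m/s; NA rows
#'   invalid) and `valid` (logical vector).
#' @export
sample_inner_velocity <- function(mesh, field, frame = 1L, depth) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(field, "velocity_field"))
  if (!is_scalar_number(depth) || depth <= 0)
    stop_flow4d("depth must be > 0 (m)", "flow4d_parameter_error")
  vals <- frame_values(field, frame)
  pts <- face_centers(mesh) - (depth * 1e3) * mesh$normals  # mm
  v <- trilinear_vector(vals, field$geometry, pts)
  valid <- stats::complete.cases(v)
  v[!valid, ] <- NA_real_
  list(velocity = v, valid = valid)
}

default_wss_depth <- function(geometry) 0.5 * mean(geometry$spacing) * 1e-3

#' Wall shear stress from near-wall velocity sampling
#'
#' The wall velocity is taken as zero (no slip); the velocity a half voxel
#' inside the wall along the inward normal is interpolated trilinearly; its
#' projection tangential to the face gives the shear direction; and the
#' finite-difference gradient over the sampling depth gives the magnitude:
#' `WSS = mu * v_tangential / depth` (Pa).
#'
#' @param mesh lumen surface [tri_mesh()] with outward normals.
#' @param field a [velocity_field()].
#' @param frame 1-based frame index.
#' @param props a [fluid_properties()].
#' @param depth sampling depth in metres; default (`NULL`) is half the mean
#'   voxel spacing ("a half voxel inner site").
#' @return An object of class `wall_shear_field`: list with `mesh`,
#'   `wss_vector` (n_faces x 3, Pa, tangential), `wss_magnitude` (Pa),
#'   `valid` (faces whose sample stayed on the grid), `depth` (m).
#' @export
compute_wss <- function(mesh, field, frame = 1L, props = fluid_properties(),
                        depth = NULL) {
  stopifnot(inherits(props, "fluid_properties"))
  depth <- depth %||% default_wss_depth(field$geometry)
  s <- sample_inner_velocity(mesh, field, frame, depth)
  v <- s$velocity
  n <- mesh$normals
  vn <- rowSums(v * n)
  tang <- v - vn * n
  wss <- props$mu * tang / depth
  mag <- row_norms(wss)
  if (!any(s$valid))
    stop_flow4d("all faces were excluded (mesh outside the velocity grid?)",
                "flow4d_value_error")
  structure(list(mesh = mesh, wss_vector = wss, wss_magnitude = mag,
                 valid = s$valid, depth = depth),
            class = "wall_shear_field")
}

#' @export
print.wall_shear_field <- function(x, ...) {
  ok <- x$valid
  cat("wall_shear_field:", sum(ok), "of", length(ok), "faces valid,",
      "area-averaged |WSS|",
      format(sum((x$wss_magnitude * x$mesh$areas)[ok]) / sum(x$mesh$areas[ok])),
      "Pa\n")
  invisible(x)
}

#' Area-averaged WSS magnitude over (a subset of) faces
#'
#' @param wss a `wall_shear_field` from [compute_wss()].
#' @param faces optional logical/integer face selector; defaults to all
#'   valid faces.
#' @return Scalar, Pa.
#' @export
mean_wss <- function(wss, faces = NULL) {
  sel <- rep(TRUE, nrow(wss$mesh$faces))
  if (!is.null(faces)) {
    sel <- rep(FALSE, nrow(wss$mesh$faces))
    sel[faces] <- TRUE
  }
  sel <- sel & wss$valid
  sum(wss$wss_magnitude[sel] * wss$mesh$areas[sel]) / sum(wss$mesh$areas[sel])
}

# ---- velocity gradients -----------------------------------------------

# stencil bookkeeping for derivatives along one axis, restricted to the
# in-mask voxels `idx` (linear indices): neighbour linear indices at +-1,
# +-2 voxels and whether each neighbour exists and is in-mask
axis_stencil <- function(m, idx, coord, axis) {
  sh <- dim(m)
  stride <- c(1L, sh[1], sh[1] * sh[2])[axis]
  n_ax <- sh[axis]
  has <- function(s) {
    ok <- if (s > 0) coord + s <= n_ax else coord + s >= 1L
    nb <- idx + s * stride
    nb[!ok] <- 1L  # safe dummy
    ok & m[nb]
  }
  # clamp into range; out-of-grid neighbours are never used (has = FALSE)
  nb <- function(s) pmin(pmax(idx + s * stride, 1L), length(m))
  list(p1 = nb(1L), m1 = nb(-1L), p2 = nb(2L), m2 = nb(-2L),
       hp1 = has(1L), hm1 = has(-1L), hp2 = has(2L), hm2 = has(-2L))
}

# derivative of u at the in-mask voxels given a precomputed axis stencil:
# central where both 6-neighbours are in-mask, one-sided (second order
# where two same-side neighbours exist, else first order) where exactly one
# side is in-mask, NA where neither.
stencil_derivative <- function(u, idx, st, h_m) {
  u0 <- u[idx]
  up1 <- u[st$p1]; um1 <- u[st$m1]
  d <- rep(NA_real_, length(idx))
  cen <- st$hp1 & st$hm1
  d[cen] <- (up1[cen] - um1[cen]) / (2 * h_m)
  fwd2 <- st$hp1 & !st$hm1 & st$hp2
  if (any(fwd2)) {
    up2 <- u[st$p2[fwd2]]
    d[fwd2] <- (-3 * u0[fwd2] + 4 * up1[fwd2] - up2) / (2 * h_m)
  }
  fwd1 <- st$hp1 & !st$hm1 & !st$hp2
  d[fwd1] <- (up1[fwd1] - u0[fwd1]) / h_m
  bwd2 <- !st$hp1 & st$hm1 & st$hm2
  if (any(bwd2)) {
    um2 <- u[st$m2[bwd2]]
    d[bwd2] <- (3 * u0[bwd2] - 4 * um1[bwd2] + um2) / (2 * h_m)
  }
  bwd1 <- !st$hp1 & st$hm1 & !st$hm2
  d[bwd1] <- (u0[bwd1] - um1[bwd1]) / h_m
  d
}

# full-array convenience wrapper (NA outside the mask)
masked_derivative <- function(u, m, axis, h_m) {
  idx <- which(m)
  coord <- arrayInd(idx, dim(m))[, axis]
  st <- axis_stencil(m, idx, coord, axis)
  d <- array(NA_real_, dim = dim(u))
  d[idx] <- stencil_derivative(u, idx, st, h_m)
  d
}

#' Strain-rate tensor of a masked velocity frame
#'
#' Computes `S_ij = (du_i/dx_j + du_j/dx_i) / 2` (1/s) by finite
#' differences restricted to the mask: central differences where both
#' face-neighbours along an axis are in-mask, one-sided differences
#' (second order where the stencil allows, first order otherwise) at the
#' lumen edge, and exclusion from the valid mask where a direction has no
#' in-mask neighbour at all.
#'
#' @param field a [velocity_field()].
#' @param frame 1-based frame index.
#' @param mask a [binary_mask()] on the same grid.
#' @return An object of class `strain_rate_volume`: list with `geometry`,
#'   `tensor` (array `[nx,ny,nz,3,3]`, 1/s, symmetric by construction) and
#'   `valid` (logical array).
#' @export
strain_rate <- function(field, frame = 1L, mask) {
  stopifnot(inherits(field, "velocity_field"), inherits(mask, "binary_mask"))
  if (!same_geometry(field$geometry, mask$geometry))
    stop_flow4d("field and mask are on different grids", "flow4d_shape_error")
  vals <- frame_values(field, frame)
  g <- field$geometry
  m <- mask$values
  sh <- g$shape
  idx <- which(m)
  ai <- arrayInd(idx, sh)
  # grad[[i]][[j]] = du_i/dx_j at the in-mask voxels
  grad <- vector("list", 3L)
  for (i in 1:3) grad[[i]] <- vector("list", 3L)
  for (j in 1:3) {
    st <- axis_stencil(m, idx, ai[, j], j)
    h_m <- g$spacing[j] * 1e-3
    for (i in 1:3)
      grad[[i]][[j]] <- stencil_derivative(vals[, , , i], idx, st, h_m)
  }
  ok <- rep(TRUE, length(idx))
  for (i in 1:3) for (j in 1:3) ok <- ok & !is.na(grad[[i]][[j]])
  valid <- array(FALSE, dim = sh)
  valid[idx[ok]] <- TRUE
  S <- array(0, dim = c(sh, 3L, 3L))
  plane <- prod(sh)
  for (i in 1:3) for (j in 1:3) {
    sv <- rep(NA_real_, plane)
    sv[idx] <- (grad[[i]][[j]] + grad[[j]][[i]]) / 2
    S[(plane * ((j - 1) * 3 + (i - 1))) + seq_len(plane)] <- sv
  }
  structure(list(geometry = g, tensor = S, valid = valid),
            class = "strain_rate_volume")
}

#' RNG k-epsilon eddy viscosity
#'
#' `mu_t = c_mu * rho * k^2 / epsilon` (Pa s), evaluated pointwise from
#' supplied turbulent kinetic energy and dissipation-rate volumes. Where
#' `epsilon` is below `eps_floor` the eddy viscosity is set to zero to
#' avoid division blow-up.
#'
#' @param k [scalar_volume()] with unit `"m^2/s^2"`, k >= 0.
#' @param epsilon [scalar_volume()] with unit `"m^2/s^3"` on the same grid.
#' @param props a [fluid_properties()] (supplies rho).
#' @param model a [closure_model()] (supplies c_mu).
#' @param eps_floor dissipation floor, m^2/s^3. Default 1e-12.
#' @return A [scalar_volume()] of eddy viscosity, unit `"Pa.s"`.
#' @export
eddy_viscosity_rng <- function(k, epsilon, props = fluid_properties(),
                               model = closure_model("rng_k_epsilon"),
                               eps_floor = 1e-12) {
  stopifnot(inherits(k, "scalar_volume"), inherits(epsilon, "scalar_volume"))
  if (!same_geometry(k$geometry, epsilon$geometry))
    stop_flow4d("k and epsilon are on different grids", "flow4d_shape_error")
  if (k$unit != "m^2/s^2" || epsilon$unit != "m^2/s^3")
    stop_flow4d("k must be m^2/s^2 and epsilon m^2/s^3", "flow4d_parameter_error")
  if (any(k$values < 0, na.rm = TRUE))
    stop_flow4d("k must be non-negative", "flow4d_value_error")
  mu_t <- model$c_mu * props$rho * k$values^2 / epsilon$values
  mu_t[is.na(epsilon$values) | epsilon$values <= eps_floor] <- 0
  mu_t[is.na(k$values)] <- 0
  scalar_volume(mu_t, k$geometry, unit = "Pa.s")
}

#' Smagorinsky LES eddy viscosity
#'
#' `mu_t = (c_s * delta)^2 * sqrt(2 * sum_ij S_ij S_ij)` (Pa s), zero
#' outside the strain volume's valid mask. `delta` is the local grid size;
#' on a structured grid the default is the cube root of the voxel volume.
#'
#' @param strain a `strain_rate_volume` from [strain_rate()].
#' @param model a [closure_model()]; its `delta` (m) overrides the default.
#' @return A [scalar_volume()] of eddy viscosity, unit `"Pa.s"`.
#' @export
eddy_viscosity_les <- function(strain, model = closure_model("les_smagorinsky")) {
  stopifnot(inherits(strain, "strain_rate_volume"))
  delta <- model$delta %||% voxel_volume_m3(strain$geometry)^(1 / 3)
  if (delta <= 0)
    stop_flow4d("delta must be > 0", "flow4d_parameter_error")
  ss <- array(0, dim = strain$geometry$shape)
  for (i in 1:3) for (j in 1:3) {
    s2 <- strain$tensor[, , , i, j]^2
    s2[is.na(s2)] <- 0
    ss <- ss + s2
  }
  mu_t <- (model$c_s * delta)^2 * sqrt(2 * ss)
  mu_t[!strain$valid] <- 0
  scalar_volume(mu_t, strain$geometry, unit = "Pa.s")
}

#' Outermost voxel shell of a mask (the MRI "boundary layer")
#'
#' @param mask a nonempty [binary_mask()].
#' @return A [binary_mask()] true exactly for foreground voxels with at
#'   least one background 6-neighbour (grid edges count as background).
#' @export
boundary_layer_mask <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$values))
    stop_flow4d("mask is empty", "flow4d_value_error")
  binary_mask(boundary_voxels(mask$values), mask$geometry)
}

#' Viscous flow energy loss with turbulence closures
#'
#' Evaluates the dissipation integral
#' `EL = sum_voxels (mu + mu_t) * sum_ij (du_i/dx_j + du_j/dx_i)^2 / 2 * dV`
#' in watts over the valid-stencil voxels of the mask, and splits it into
#' the boundary-layer shell ([boundary_layer_mask()]) and the core. The
#' eddy viscosity `mu_t` is zero for the laminar closure, computed via
#' [eddy_viscosity_les()] for the Smagorinsky closure, and must be supplied
#' (from external k/epsilon fields, see [eddy_viscosity_rng()]) for the
#' RNG k-epsilon closure.
#'
#' @param field a [velocity_field()].
#' @param frame 1-based frame index.
#' @param mask integration domain, a [binary_mask()].
#' @param props a [fluid_properties()].
#' @param model a [closure_model()].
#' @param mu_t optional [scalar_volume()] (`"Pa.s"`) of eddy viscosity,
#'   required for `rng_k_epsilon`.
#' @return An object of class `energy_loss_result`: list with `el_total`,
#'   `el_boundary_layer`, `el_core` (W), `closure`,
#'   `includes_eddy_viscosity`, and `voxel_count` (valid voxels per
#'   compartment).
#' @export
compute_el <- function(field, frame = 1L, mask, props = fluid_properties(),
                       model = closure_model("laminar"), mu_t = NULL) {
  stopifnot(inherits(model, "closure_model"), inherits(props, "fluid_properties"))
  S <- strain_rate(field, frame, mask)
  if (model$kind == "laminar") {
    mu_t_vals <- 0
  } else if (model$kind == "les_smagorinsky") {
    mu_t_vals <- eddy_viscosity_les(S, model)$values
  } else {
    if (is.null(mu_t))
      stop_flow4d("RNG k-epsilon closure needs a supplied mu_t volume",
                  "flow4d_parameter_error")
    stopifnot(inherits(mu_t, "scalar_volume"))
    if (!same_geometry(mu_t$geometry, field$geometry))
      stop_flow4d("mu_t is on a different grid", "flow4d_shape_error")
    if (mu_t$unit != "Pa.s")
      stop_flow4d("mu_t must have unit Pa.s", "flow4d_parameter_error")
    if (any(mu_t$values < 0, na.rm = TRUE))
      stop_flow4d("mu_t must be non-negative", "flow4d_value_error")
    mu_t_vals <- mu_t$values
    mu_t_vals[is.na(mu_t_vals)] <- 0
  }
  # dissipation function: sum_ij 1/2 (du_i/dx_j + du_j/dx_i)^2 = 2 S_ij S_ij
  phi <- array(0, dim = S$geometry$shape)
  for (i in 1:3) for (j in 1:3) {
    s2 <- S$tensor[, , , i, j]^2
    s2[is.na(s2)] <- 0
    phi <- phi + 2 * s2
  }
  mu_eff <- props$mu + mu_t_vals
  dens <- mu_eff * phi * voxel_volume_m3(field$geometry)  # W per voxel
  bl <- boundary_layer_mask(mask)$values
  v_bl <- S$valid & bl
  v_core <- S$valid & !bl
  el_bl <- sum(dens[v_bl])
  el_core <- sum(dens[v_core])
  structure(list(el_total = el_bl + el_core,
                 el_boundary_layer = el_bl,
                 el_core = el_core,
                 closure = model,
                 includes_eddy_viscosity = model$kind != "laminar",
                 voxel_count = c(boundary_layer = sum(v_bl),
                                 core = sum(v_core))),
            class = "energy_loss_result")
}

#' @export
print.energy_loss_result <- function(x, ...) {
  cat(sprintf("energy_loss_result (%s): total %.4g W = boundary layer %.4g W + core %.4g W (%d + %d voxels)\n",
              x$closure$kind, x$el_total, x$el_boundary_layer, x$el_core,
              x$voxel_count[1], x$voxel_count[2]))
  invisible(x)
}

#' Volume and mass flow through a plane
#'
#' Rasterizes the plane at the in-plane voxel resolution, samples the
#' velocity trilinearly at each raster point, keeps points where the
#' trilinearly interpolated mask is >= 0.5, and integrates the normal
#' velocity component: `Q = sum (v . n) * dA`. The sign follows the
#' supplied normal.
#'
#' @param field a [velocity_field()].
#' @param frame 1-based frame index.
#' @param mask lumen [binary_mask()] on the same grid.
#' @param plane list with `origin` (mm 3-vector) and `normal` (3-vector,
#'   normalized internally).
#' @param props a [fluid_properties()] (supplies rho for the mass flow).
#' @return List with `volume_flow` (m^3/s), `mass_flow` (kg/s),
#'   `n_samples` (raster points inside the lumen), `area` (sampled lumen
#'   cross-section, m^2).
#' @export
flow_rate <- function(field, frame = 1L, mask, plane,
                      props = fluid_properties()) {
  stopifnot(inherits(field, "velocity_field"), inherits(mask, "binary_mask"))
  if (!same_geometry(field$geometry, mask$geometry))
    stop_flow4d("field and mask are on different grids", "flow4d_shape_error")
  o <- as.numeric(plane$origin)
  nrm <- as.numeric(plane$normal)
  if (length(o) != 3L || length(nrm) != 3L || sum(nrm^2) == 0)
    stop_flow4d("plane needs origin and a nonzero normal", "flow4d_parameter_error")
  nrm <- nrm / sqrt(sum(nrm^2))
  # orthonormal in-plane basis
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * nrm) * nrm
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  g <- field$geometry
  h <- min(g$spacing)  # mm, raster pitch
  # raster extent: project grid bounding box corners onto (e1, e2)
  corners <- voxel_centers(g, as.matrix(expand.grid(c(1, g$shape[1]),
                                                    c(1, g$shape[2]),
                                                    c(1, g$shape[3]))))
  rel <- sweep(corners, 2, o, "-")
  s1 <- rel %*% e1
  s2 <- rel %*% e2
  u <- seq(floor(min(s1) / h) * h, ceiling(max(s1) / h) * h, by = h)
  v <- seq(floor(min(s2) / h) * h, ceiling(max(s2) / h) * h, by = h)
  gr <- expand.grid(u = u, v = v)
  pts <- outer(gr$u, e1) + outer(gr$v, e2)
  pts <- sweep(pts, 2, o, "+")
  mnum <- array(0, dim = g$shape)
  mnum[mask$values] <- 1
  inm <- trilinear_scalar(mnum, g, pts)
  keep <- !is.na(inm) & inm >= 0.5
  if (!any(keep))
    stop_flow4d("plane does not intersect the mask", "flow4d_value_error")
  vel <- trilinear_vector(frame_values(field, frame), g, pts[keep, , drop = FALSE])
  vn <- vel %*% nrm
  vn[is.na(vn)] <- 0
  dA <- (h * 1e-3)^2  # m^2
  q <- sum(vn) * dA
  list(volume_flow = q, mass_flow = props$rho * q,
       n_samples = sum(keep), area = sum(keep) * dA)
}

#' Cubic-spline interpolation of a flow waveform
#'
#' Fits a cubic spline through (time, flow) samples, as used to turn
#' per-phase plane-integrated flows into a continuous inlet waveform.
#' Evaluation outside the sampled interval is an error (the spline is an
#' interpolant, not an extrapolant).
#'
#' @param times strictly increasing sample times, s (>= 4 samples).
#' @param flows flow samples (same length).
#' @return A function `flow(t)` defined on `[min(times), max(times)]`.
#' @export
interpolate_waveform <- function(times, flows) {
  times <- as.numeric(times)
  flows <- as.numeric(flows)
  if (length(times) < 4L)
    stop_flow4d("need at least 4 waveform samples", "flow4d_parameter_error")
  if (length(flows) != length(times))
    stop_flow4d("times and flows differ in length", "flow4d_parameter_error")
  if (any(diff(times) <= 0))
    stop_flow4d("times must be strictly increasing", "flow4d_value_error")
  f <- stats::splinefun(times, flows, method = "fmm")
  lo <- min(times); hi <- max(times)
  function(t) {
    t <- as.numeric(t)
    if (any(t < lo - 1e-12) || any(t > hi + 1e-12))
      stop_flow4d("waveform evaluated outside the sampled time range",
                  "flow4d_value_error")
    f(t)
  }
}
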