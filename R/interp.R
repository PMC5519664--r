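# Trilinear interpolation on regular grids.
#
# Points are world positions in mm; values live at voxel centres. Points
# outside the hull of voxel centres return NA. A small tolerance keeps
# points sitting exactly on the boundary inside. NA corner values propagate
# to NA results (missing data never fabricates a number).

EDGE_TOL <- 1e-9

# arr: [nx,ny,nz]; geometry: grid_geometry; pts: n x 3 world mm
trilinear_scalar <- function(arr, geometry, pts) {
  t0 <- world_to_index0(geometry, pts)  # continuous 0-based index
  n <- geometry$shape
  out <- rep(NA_real_, nrow(t0))
  inside <- t0[, 1] >= -EDGE_TOL & t0[, 1] <= n[1] - 1 + EDGE_TOL &
            t0[, 2] >= -EDGE_TOL & t0[, 2] <= n[2] - 1 + EDGE_TOL &
            t0[, 3] >= -EDGE_TOL & t0[, 3] <= n[3] - 1 + EDGE_TOL
  if (!any(inside)) return(out)
  t0 <- t0[inside, , drop = FALSE]
  # clamp so the base voxel of boundary points stays in range
  i0 <- pmin(pmax(floor(t0[, 1]), 0), n[1] - 2L + (n[1] == 1L))
  j0 <- pmin(pmax(floor(t0[, 2]), 0), n[2] - 2L + (n[2] == 1L))
  k0 <- pmin(pmax(floor(t0[, 3]), 0), n[3] - 2L + (n[3] == 1L))
  fx <- pmin(pmax(t0[, 1] - i0, 0), 1)
  fy <- pmin(pmax(t0[, 2] - j0, 0), 1)
  fz <- pmin(pmax(t0[, 3] - k0, 0), 1)
  acc <- numeric(nrow(t0))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    ii <- pmin(i0 + dx, n[1] - 1) + 1L
    jj <- pmin(j0 + dy, n[2] - 1) + 1L
    kk <- pmin(k0 + dz, n[3] - 1) + 1L
    v <- arr[cbind(ii, jj, kk)]
    # corners with zero weight may be NA without harm
    contrib <- w * v
    contrib[w == 0] <- 0
    acc <- acc + contrib
  }
  out[inside] <- acc
  out
}

# vals4: [nx,ny,nz,3] one velocity frame; returns n x 3 matrix (NA outside)
trilinear_vector <- function(vals4, geometry, pts) {
  cbind(trilinear_scalar(vals4[, , , 1], geometry, pts),
        trilinear_scalar(vals4[, , , 2], geometry, pts),
        trilinear_scalar(vals4[, , , 3], geometry, pts))
}
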