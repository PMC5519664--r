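#' Resample a velocity field onto another grid
#'
#' Linear interpolation of the source field at the masked target voxel
#' centres, the standard step for bringing a simulated velocity field onto
#' the MRI structure grid before voxelwise comparison. Grid sources are
#' interpolated trilinearly; scattered point-cloud sources (a data.frame
#' with columns `x, y, z` in mm and `u, v, w` in m/s) fall back to
#' inverse-distance weighting of the `k` nearest samples, since no
#' scattered linear interpolant is available in the supported stack.
#'
#' Target voxels outside the mask or outside the source support are marked
#' missing (`NA`).
#'
#' @param source a [velocity_field()] or a point-cloud data.frame.
#' @param target a [grid_geometry()].
#' @param target_mask a [binary_mask()] on the target grid.
#' @param frame source frame used (grid sources), default 1.
#' @param k neighbours for the point-cloud fallback, default 8.
#' @return A single-frame [velocity_field()] on the target grid.
#' @export
resample_to_grid <- function(source, target, target_mask, frame = 1L, k = 8L) {
  stopifnot(inherits(target, "grid_geometry"), inherits(target_mask, "binary_mask"))
  if (!same_geometry(target, target_mask$geometry))
    stop_flow4d("target mask is on a different grid", "flow4d_shape_error")
  idx <- which(target_mask$values, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop_flow4d("target mask is empty", "flow4d_value_error")
  pts <- voxel_centers(target, idx)
  if (inherits(source, "velocity_field")) {
    v <- trilinear_vector(frame_values(source, frame), source$geometry, pts)
  } else {
    pc <- as.data.frame(source)
    need <- c("x", "y", "z", "u", "v", "w")
    if (!all(need %in% names(pc)))
      stop_flow4d("point cloud needs columns x, y, z (mm), u, v, w (m/s)",
                  "flow4d_parameter_error")
    v <- idw_interpolate(as.matrix(pc[, c("x", "y", "z")]),
                         as.matrix(pc[, c("u", "v", "w")]), pts, k)
  }
  if (all(is.na(v)))
    stop_flow4d("source does not overlap the masked target voxels",
                "flow4d_value_error")
  out <- array(NA_real_, dim = c(target$shape, 3L))
  for (d in 1:3) {
    a <- array(NA_real_, dim = target$shape)
    a[idx] <- v[, d]
    out[, , , d] <- a
  }
  velocity_field(out, target, times = 0)
}

# inverse-distance weighting, k nearest; exact hit returns the sample value
idw_interpolate <- function(xyz, uvw, pts, k) {
  k <- min(k, nrow(xyz))
  out <- matrix(NA_real_, nrow(pts), 3L)
  for (p in seq_len(nrow(pts))) {
    d2 <- colSums((t(xyz) - pts[p, ])^2)
    nn <- order(d2)[seq_len(k)]
    if (d2[nn[1]] < 1e-18) {
      out[p, ] <- uvw[nn[1], ]
    } else {
      w <- 1 / d2[nn]
      out[p, ] <- colSums(uvw[nn, , drop = FALSE] * w) / sum(w)
    }
  }
  out
}

#' Partition a lumen mask into three regions by two cut planes
#'
#' Voxels on the negative side of plane 1 are labelled `AAo`, voxels
#' between the planes `Arch`, voxels past plane 2 `DAo`; background voxels
#' are `excluded`. Plane placement is the caller's anatomical convention;
#' the planes must be ordered along the vessel.
#'
#' @param mask a [binary_mask()].
#' @param plane1,plane2 lists with `origin` (mm) and `normal`; the normals
#'   should point from AAo toward DAo.
#' @return An object of class `region_partition`: list with `geometry` and
#'   `labels` (character array: `"AAo"`, `"Arch"`, `"DAo"`, `"excluded"`).
#' @export
partition_regions <- function(mask, plane1, plane2) {
  stopifnot(inherits(mask, "binary_mask"))
  p1o <- as.numeric(plane1$origin); p1n <- as.numeric(plane1$normal)
  p2o <- as.numeric(plane2$origin); p2n <- as.numeric(plane2$normal)
  if (sum(p1n^2) == 0 || sum(p2n^2) == 0)
    stop_flow4d("plane normals must be nonzero", "flow4d_parameter_error")
  p1n <- p1n / sqrt(sum(p1n^2)); p2n <- p2n / sqrt(sum(p2n^2))
  if (all(abs(p1o - p2o) < 1e-12) && all(abs(p1n - p2n) < 1e-12))
    stop_flow4d("the two cut planes are identical", "flow4d_parameter_error")
  ctr <- voxel_centers(mask$geometry)
  s1 <- sweep(ctr, 2, p1o, "-") %*% p1n
  s2 <- sweep(ctr, 2, p2o, "-") %*% p2n
  lab <- ifelse(s1 < 0, "AAo", ifelse(s2 < 0, "Arch", "DAo"))
  lab[!as.vector(mask$values)] <- "excluded"
  structure(list(geometry = mask$geometry,
                 labels = array(lab, dim = mask$geometry$shape)),
            class = "region_partition")
}

#' Region-wise Pearson correlation and error between two velocity fields
#'
#' For each region (AAo, Arch, DAo) and velocity component (u/AP, v/RL,
#' w/SI), computes the Pearson product-moment correlation coefficient with
#' its two-sided p-value and the mean and SD of the absolute per-voxel
#' component difference (m/s) over voxels where both fields are
#' non-missing. Cells with fewer than 2 joint samples are reported as
#' `NA`, not raised as errors.
#'
#' @param a,b single-frame [velocity_field()]s on the same grid.
#' @param partition a `region_partition` from [partition_regions()].
#' @param frame_a,frame_b frames to compare, default 1.
#' @return A `comparison_report`: data.frame with columns `region`,
#'   `component`, `n`, `r`, `p_value`, `mean_abs_error`, `sd_abs_error`
#'   (errors in m/s).
#' @export
compare_fields <- function(a, b, partition, frame_a = 1L, frame_b = 1L) {
  stopifnot(inherits(a, "velocity_field"), inherits(b, "velocity_field"),
            inherits(partition, "region_partition"))
  if (!same_geometry(a$geometry, b$geometry) ||
      !same_geometry(a$geometry, partition$geometry))
    stop_flow4d("fields and partition must share one grid", "flow4d_shape_error")
  va <- frame_values(a, frame_a)
  vb <- frame_values(b, frame_b)
  comp_names <- c("u (AP)", "v (RL)", "w (SI)")
  regions <- c("AAo", "Arch", "DAo")
  rows <- list()
  for (reg in regions) {
    in_reg <- partition$labels == reg
    for (d in 1:3) {
      xa <- va[, , , d][in_reg]
      xb <- vb[, , , d][in_reg]
      ok <- !is.na(xa) & !is.na(xb)
      n <- sum(ok)
      r <- p <- mae <- sdae <- NA_real_
      if (n >= 2L) {
        xa_ <- xa[ok]; xb_ <- xb[ok]
        if (stats::sd(xa_) > 0 && stats::sd(xb_) > 0) {
          r <- stats::cor(xa_, xb_)
          if (n >= 3L)
            p <- stats::cor.test(xa_, xb_, method = "pearson")$p.value
        }
        ae <- abs(xa_ - xb_)
        mae <- mean(ae)
        sdae <- stats::sd(ae)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(region = reg, component = comp_names[d], n = n, r = r,
                   p_value = p, mean_abs_error = mae, sd_abs_error = sdae,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_report", "data.frame")
  attr(out, "units") <- c(mean_abs_error = "m/s", sd_abs_error = "m/s")
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report (errors in m/s):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
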