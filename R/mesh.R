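#' Triangle surface mesh
#'
#' Vertices are world positions in mm; faces are 1-based vertex index
#' triples wound so that the right-hand-rule normal points outward (from
#' lumen to exterior). Per-face unit normals and areas (mm^2) are computed
#' on construction; degenerate (zero-area) faces are rejected.
#'
#' @param vertices numeric n x 3 matrix, mm.
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @return An object of class `tri_mesh` with elements `vertices`, `faces`,
#'   `normals` (unit, per face), `areas` (mm^2, per face).
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L)
  faces <- matrix(as.integer(faces), ncol = 3L)
  if (nrow(vertices) < 3L || nrow(faces) < 1L)
    stop_flow4d("mesh needs >= 3 vertices and >= 1 face", "flow4d_value_error")
  if (any(!is.finite(vertices)))
    stop_flow4d("vertex coordinates must be finite", "flow4d_value_error")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop_flow4d("face indices out of range", "flow4d_index_error")
  g <- face_geometry(vertices, faces)
  if (any(g$areas <= 0))
    stop_flow4d("mesh contains degenerate zero-area faces", "flow4d_value_error")
  structure(list(vertices = vertices, faces = faces,
                 normals = g$normals, areas = g$areas),
            class = "tri_mesh")
}

face_geometry <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  cr <- cross3(b - a, c_ - a)
  nr <- row_norms(cr)
  list(normals = cr / ifelse(nr == 0, 1, nr), areas = nr / 2)
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("tri_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces, area", format(mesh_area(x)), "mm^2\n")
  invisible(x)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [tri_mesh()].
#' @export
mesh_area <- function(mesh) sum(mesh$areas)

#' Face centroids of a mesh (mm)
#' @param mesh a [tri_mesh()].
#' @export
face_centers <- function(mesh) {
  (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
}

#' Enclosed volume of a closed mesh (mm^3)
#'
#' Signed-tetrahedron sum; positive for a watertight mesh with outward
#' normals.
#' @param mesh a [tri_mesh()].
#' @export
mesh_volume <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  sum(rowSums(a * cross3(b, c_))) / 6
}

#' Is every mesh edge shared by exactly two faces?
#' @param mesh a [tri_mesh()].
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Uniform Laplacian mesh smoothing
#'
#' Each iteration moves every vertex toward the centroid of its topological
#' neighbours by a factor `lambda`:
#' `v <- v + lambda * (mean(neighbours) - v)`. Topology is unchanged;
#' normals and areas are recomputed. This is the classic smoothing pass
#' applied to staircase isosurfaces of voxel segmentations; it mildly
#' shrinks closed surfaces, so keep `iterations` moderate.
#'
#' @param mesh a [tri_mesh()].
#' @param iterations non-negative integer, default 10.
#' @param lambda smoothing weight in (0, 1], default 0.5.
#' @return A smoothed [tri_mesh()].
#' @export
smooth_laplacian <- function(mesh, iterations = 10L, lambda = 0.5) {
  if (!is_scalar_number(iterations) || iterations < 0 ||
      iterations != round(iterations))
    stop_flow4d("iterations must be a non-negative integer", "flow4d_parameter_error")
  if (!is_scalar_number(lambda) || lambda <= 0 || lambda > 1)
    stop_flow4d("lambda must lie in (0, 1]", "flow4d_parameter_error")
  if (iterations == 0L) return(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  # undirected unique edges
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  src <- c(e[, 1], e[, 2])
  dst <- c(e[, 2], e[, 1])
  deg <- tabulate(src, nbins = nrow(v))
  deg[deg == 0] <- 1
  for (it in seq_len(iterations)) {
    rs <- rowsum(v[dst, , drop = FALSE], src, reorder = TRUE)
    idx <- as.integer(rownames(rs))
    nb <- v  # isolated vertices (none in practice) stay put
    nb[idx, ] <- rs / deg[idx]
    v <- v + lambda * (nb - v)
  }
  tri_mesh(v, f)
}
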