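# Independent oracles, deliberately naive: these re-derive expected values
# by brute force and must not share code paths with the package internals.

# flood fill by explicit queue (connected component of `mask` containing seed)
oracle_flood_fill <- function(mask, seed, connectivity = 26L) {
  sh <- dim(mask)
  offs <- if (connectivity == 6L) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, ]
  }
  out <- array(FALSE, dim = sh)
  if (!mask[seed[1], seed[2], seed[3]]) return(out)
  queue <- list(seed)
  out[seed[1], seed[2], seed[3]] <- TRUE
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    for (r in seq_len(nrow(offs))) {
      w <- v + offs[r, ]
      if (any(w < 1) || any(w > sh)) next
      if (mask[w[1], w[2], w[3]] && !out[w[1], w[2], w[3]]) {
        out[w[1], w[2], w[3]] <- TRUE
        queue[[length(queue) + 1]] <- w
      }
    }
  }
  out
}

# triple-loop evaluation of the viscous dissipation integral with the same
# stated stencil rules (central / one-sided second order / one-sided first
# order / exclude), written independently against a plain array
oracle_el_laminar <- function(vals, mask, spacing_mm, mu) {
  sh <- dim(mask)
  h <- spacing_mm * 1e-3
  inm <- function(i, j, k) {
    i >= 1 && i <= sh[1] && j >= 1 && j <= sh[2] && k >= 1 && k <= sh[3] &&
      mask[i, j, k]
  }
  deriv <- function(comp, i, j, k, ax) {
    e <- c(0, 0, 0); e[ax] <- 1
    p1 <- c(i, j, k) + e; m1 <- c(i, j, k) - e
    p2 <- c(i, j, k) + 2 * e; m2 <- c(i, j, k) - 2 * e
    hp1 <- inm(p1[1], p1[2], p1[3]); hm1 <- inm(m1[1], m1[2], m1[3])
    u0 <- vals[i, j, k, comp]
    if (hp1 && hm1) {
      return((vals[p1[1], p1[2], p1[3], comp] - vals[m1[1], m1[2], m1[3], comp]) / (2 * h[ax]))
    }
    if (hp1) {
      u1 <- vals[p1[1], p1[2], p1[3], comp]
      if (inm(p2[1], p2[2], p2[3])) {
        u2 <- vals[p2[1], p2[2], p2[3], comp]
        return((-3 * u0 + 4 * u1 - u2) / (2 * h[ax]))
      }
      return((u1 - u0) / h[ax])
    }
    if (hm1) {
      u1 <- vals[m1[1], m1[2], m1[3], comp]
      if (inm(m2[1], m2[2], m2[3])) {
        u2 <- vals[m2[1], m2[2], m2[3], comp]
        return((3 * u0 - 4 * u1 + u2) / (2 * h[ax]))
      }
      return((u0 - u1) / h[ax])
    }
    NA_real_
  }
  vvol <- prod(h)
  el <- 0
  for (i in seq_len(sh[1])) for (j in seq_len(sh[2])) for (k in seq_len(sh[3])) {
    if (!mask[i, j, k]) next
    G <- matrix(NA_real_, 3, 3)
    for (ci in 1:3) for (ax in 1:3) G[ci, ax] <- deriv(ci, i, j, k, ax)
    if (any(is.na(G))) next
    phi <- 0
    for (ci in 1:3) for (ax in 1:3) phi <- phi + 0.5 * (G[ci, ax] + G[ax, ci])^2
    el <- el + mu * phi * vvol
  }
  el
}

# textbook Pearson correlation (sum formula)
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# voxelized ball mask of radius r_mm centred in an isotropic grid
make_ball <- function(r_mm = 10, spacing = 1) {
  n <- 2L * as.integer(ceiling((r_mm + 2 * spacing) / spacing)) + 1L
  half <- (n - 1L) / 2
  g <- grid_geometry(c(n, n, n), rep(spacing, 3), origin = rep(-half * spacing, 3))
  ctr <- voxel_centers(g)
  binary_mask(array(rowSums(ctr^2) <= r_mm^2, dim = g$shape), g)
}

# smooth random in-mask velocity field on a small grid (for equivalence tests)
make_random_field <- function(sh = c(6, 6, 6), seed = 42, vmax = 0.5) {
  set.seed(seed)
  g <- grid_geometry(sh, c(1, 1, 1))
  vals <- array(stats::runif(prod(sh) * 3, -vmax, vmax), dim = c(sh, 3L))
  mask <- array(stats::runif(prod(sh)) > 0.3, dim = sh)
  # keep at least a few voxels
  mask[2:4, 2:4, 2:4] <- TRUE
  list(field = velocity_field(vals, g), mask = binary_mask(mask, g), geometry = g)
}
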