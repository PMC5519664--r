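# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_flow4d <- function(msg, class) {
  stop(structure(
    class = c(class, "flow4d_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# run `code` with a private RNG stream; the session RNG state is untouched
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# shift a 3-D array by (dx, dy, dz) voxels, padding with `fill`;
# result[i,j,k] = a[i - dx, j - dy, k - dz]
shift3 <- function(a, dx, dy, dz, fill = 0) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3L)
  off <- c(dx, dy, dz)
  for (ax in 1:3) {
    n <- d[ax]
    if (abs(off[ax]) >= n) return(out)
    if (off[ax] >= 0) {
      dst[[ax]] <- (1L + off[ax]):n
      src[[ax]] <- 1L:(n - off[ax])
    } else {
      dst[[ax]] <- 1L:(n + off[ax])
      src[[ax]] <- (1L - off[ax]):n
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# neighbor offsets for 6- or 26-connectivity
neighbor_offsets <- function(connectivity) {
  if (connectivity == 6L) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else if (connectivity == 26L) {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else {
    stop_flow4d("connectivity must be 6 or 26", "flow4d_parameter_error")
  }
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# cross product of rows of two n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norms <- function(m) sqrt(rowSums(m * m))

normalize_rows <- function(m) {
  n <- row_norms(m)
  n[n == 0] <- 1
  m / n
}
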