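# internal helpers shared across modules

# evaluate a piecewise-linear curve with clamping at the endpoints
.curveEval <- function(xs, ys, x) {
  stats::approx(xs, ys, xout = x, rule = 2, ties = "ordered")$y
}

# run code under a temporary RNG state; restores the caller's stream
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# world coordinates (mm) of voxel centres along each axis
.axisCoords <- function(shape, spacing, origin) {
  lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 1) * spacing[a])
}

# centroid (mm) of a logical mask on a volume grid
maskCentroid <- function(mask, spacing, origin) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot take the centroid of an empty mask")
  origin + (colMeans(idx) - 1) * spacing
}

# trilinear interpolation of a 3-D array at continuous voxel index `p`
# (0-based, voxel centres at integer indices); error outside the grid
.trilinear <- function(arr, p) {
  d <- dim(arr)
  if (any(p < -1e-9) || any(p > d - 1 + 1e-9))
    stop("interpolation point outside the grid")
  p <- pmin(pmax(p, 0), d - 1)
  i0 <- pmin(floor(p), d - 2); i0 <- pmax(i0, 0)
  f <- p - i0
  i0 <- as.integer(i0) + 1L  # to 1-based corner
  g <- function(dx, dy, dz) arr[i0[1] + dx, i0[2] + dy, i0[3] + dz]
  c00 <- g(0,0,0) * (1 - f[1]) + g(1,0,0) * f[1]
  c10 <- g(0,1,0) * (1 - f[1]) + g(1,1,0) * f[1]
  c01 <- g(0,0,1) * (1 - f[1]) + g(1,0,1) * f[1]
  c11 <- g(0,1,1) * (1 - f[1]) + g(1,1,1) * f[1]
  c0 <- c00 * (1 - f[2]) + c10 * f[2]
  c1 <- c01 * (1 - f[2]) + c11 * f[2]
  c0 * (1 - f[3]) + c1 * f[3]
}
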