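# Trilinear gather/scatter between cubic reciprocal grids and arbitrary
# q-points, and bilinear image sampling.  Shared by slicing (volume ->
# pattern), merging (pattern -> volume) and the polar transform.

# points: m x 3 matrix of 1-based fractional voxel coordinates.
# Returns the 8 corner linear indices (m x 8), weights (m x 8) and an
# in-bounds flag per point.
.tri_corners <- function(pts, n) {
  i0 <- floor(pts)
  f <- pts - i0
  ok <- i0[, 1] >= 1 & i0[, 2] >= 1 & i0[, 3] >= 1 &
    i0[, 1] <= n - 1 & i0[, 2] <= n - 1 & i0[, 3] <= n - 1
  i0[!ok, ] <- 1  # placeholder, excluded via ok
  wx <- cbind(1 - f[, 1], f[, 1])
  wy <- cbind(1 - f[, 2], f[, 2])
  wz <- cbind(1 - f[, 3], f[, 3])
  idx <- matrix(0L, nrow(pts), 8)
  wt <- matrix(0, nrow(pts), 8)
  k <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    k <- k + 1
    idx[, k] <- (i0[, 1] + dx) + n * ((i0[, 2] + dy) - 1) +
      n * n * ((i0[, 3] + dz) - 1)
    wt[, k] <- wx[, dx + 1] * wy[, dy + 1] * wz[, dz + 1]
  }
  list(idx = idx, wt = wt, ok = ok)
}

# Trilinear interpolation of `volume` at q-points (m x 3, 1/Angstrom).
# A point is valid only if in bounds and all corner voxels with weight are
# covered.  Returns list(value, valid).
.slice_values <- function(volume, qpts) {
  n <- dim(volume$data)[1]
  ctr <- floor(n / 2) + 1
  pts <- qpts / volume$dq + ctr
  tc <- .tri_corners(pts, n)
  vals <- matrix(volume$data[tc$idx], nrow(tc$idx), 8)
  out <- rowSums(vals * tc$wt)
  valid <- tc$ok
  if (!is.null(volume$coverage)) {
    cov <- matrix(volume$coverage[tc$idx], nrow(tc$idx), 8)
    valid <- valid & (rowSums((!cov) * (tc$wt > 1e-12)) == 0)
  }
  out[!valid] <- 0
  list(value = out, valid = valid)
}

# Trilinear scatter-add of `values` at q-points into an n^3 accumulator.
# Returns list(sum, weight) arrays; out-of-bounds points are dropped.
.scatter_values <- function(n, dq, qpts, values, weights = 1) {
  ctr <- floor(n / 2) + 1
  pts <- qpts / dq + ctr
  tc <- .tri_corners(pts, n)
  keep <- tc$ok
  idx <- as.vector(tc$idx[keep, , drop = FALSE])
  wt <- as.vector(tc$wt[keep, , drop = FALSE] * weights)
  val <- rep(values[keep], 8) * wt
  acc_v <- rowsum(val, idx)
  acc_w <- rowsum(wt, idx)
  s <- array(0, c(n, n, n)); w <- array(0, c(n, n, n))
  at <- as.integer(rownames(acc_v))
  s[at] <- acc_v
  w[at] <- acc_w
  list(sum = s, weight = w)
}

# Bilinear sampling of a masked image at fractional pixel coordinates
# (x = row, y = column).  Valid only when all four neighbors are inside and
# unmasked.  Returns list(value, valid).
.bilinear_sample <- function(image, mask, x, y) {
  h <- nrow(image); w <- ncol(image)
  i0 <- floor(x); j0 <- floor(y)
  ok <- i0 >= 1 & j0 >= 1 & i0 <= h - 1 & j0 <= w - 1
  i0[!ok] <- 1; j0[!ok] <- 1
  fx <- x - i0; fy <- y - j0
  id <- function(di, dj) (i0 + di) + h * (j0 + dj - 1)
  v <- image[id(0, 0)] * (1 - fx) * (1 - fy) +
    image[id(1, 0)] * fx * (1 - fy) +
    image[id(0, 1)] * (1 - fx) * fy +
    image[id(1, 1)] * fx * fy
  valid <- ok
  if (!is.null(mask)) {
    valid <- valid & mask[id(0, 0)] & mask[id(1, 0)] &
      mask[id(0, 1)] & mask[id(1, 1)]
  }
  v[!valid] <- 0
  list(value = v, valid = valid)
}
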