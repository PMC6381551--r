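## Internal array utilities: shifts, separable Gaussian smoothing,
## block averaging, trilinear interpolation.

# Shift a 3D array by `t` voxels along dimension `d`, replicating edges.
shiftArray <- function(a, t, d) {
  n <- dim(a)[d]
  idx <- pmin(pmax(seq_len(n) + t, 1L), n)
  switch(d,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

gaussKernel1d <- function(sigmaVox) {
  if (sigmaVox <= 0) return(1)
  m <- max(1L, as.integer(ceiling(3 * sigmaVox)))
  k <- stats::dnorm(seq(-m, m), sd = sigmaVox)
  k / sum(k)
}

# Convolve along one dimension with a symmetric kernel, edge-replicated.
convolveDim <- function(a, kernel, d) {
  if (length(kernel) == 1) return(a)
  m <- (length(kernel) - 1L) / 2L
  out <- array(0, dim(a))
  for (t in seq_along(kernel)) {
    w <- kernel[t]
    if (w == 0) next
    out <- out + w * shiftArray(a, t - m - 1L, d)
  }
  out
}

# Separable Gaussian smoothing; sigmaVox is per-axis (length 3, voxels).
# A zero component skips that axis.
gaussSmooth3d <- function(a, sigmaVox) {
  for (d in 1:3) {
    if (sigmaVox[d] > 0)
      a <- convolveDim(a, gaussKernel1d(sigmaVox[d]), d)
  }
  a
}

# Block-average an array whose dims are (nx*fx, ny*fy, nz*fz) down to
# (nx, ny, nz) by mean over each fx x fy x fz block.
blockMean3d <- function(a, f) {
  d <- dim(a)
  n <- d %/% f
  stopifnot(all(n * f == d))
  dim(a) <- c(f[1], n[1], f[2], n[2], f[3], n[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(prod(f), prod(n))
  array(colMeans(a), dim = n)
}

# Separable trilinear interpolation of a 3D lattice `a` (node
# coordinates in the equally spaced axis vectors xs, ys, zs) onto the
# tensor grid qx x qy x qz. Queries outside the lattice are clamped.
gridTrilinear <- function(a, xs, ys, zs, qx, qy, qz) {
  interpIdx <- function(v, q) {
    h <- v[2] - v[1]
    u <- (q - v[1]) / h
    u <- pmin(pmax(u, 0), length(v) - 1 - 1e-9)
    i0 <- floor(u)
    list(i = as.integer(i0) + 1L, w = u - i0)
  }
  ix <- interpIdx(xs, qx); iy <- interpIdx(ys, qy); iz <- interpIdx(zs, qz)
  out <- array(0, c(length(qx), length(qy), length(qz)))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wx <- if (cx) ix$w else 1 - ix$w
    wy <- if (cy) iy$w else 1 - iy$w
    wz <- if (cz) iz$w else 1 - iz$w
    corner <- a[ix$i + cx, iy$i + cy, iz$i + cz, drop = FALSE]
    w <- outer(outer(wx, wy), wz)
    out <- out + w * corner
  }
  out
}

# Bounding box (list of index ranges) of TRUE voxels in a logical array.
maskBoundingBox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0) stop("empty mask", call. = FALSE)
  lapply(1:3, function(d) range(w[, d]))
}
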