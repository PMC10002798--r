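# Internal numerical helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# World coordinate (cm) of each voxel center along an axis, origin at the
# grid center: (i - 1 - (n-1)/2) * vox for 1-based index i.
axisCoords <- function(n, vox) (seq_len(n) - 1 - (n - 1) / 2) * vox

# DFT frequencies in cycles/sample, standard fft ordering.
fftFreq <- function(n) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / n
}

# Truncated, normalized Gaussian kernel (radius 3 sigma).
gaussKernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  if (sigma < 1e-8) return(1)
  t <- seq(-radius, radius)
  k <- exp(-0.5 * (t / sigma)^2)
  k / sum(k)
}

# Separable Gaussian smoothing of a 3-D array (zero padding at edges).
gaussSmooth3d <- function(vol, sigmaVox) {
  k <- gaussKernel1d(sigmaVox)
  r <- (length(k) - 1) / 2
  if (r == 0) return(vol)
  d <- dim(vol)
  bmat <- function(n) {
    B <- matrix(0, n, n)
    for (t in -r:r) {
      idx <- seq_len(n)
      src <- idx + t
      ok <- src >= 1 & src <= n
      B[cbind(idx[ok], src[ok])] <- B[cbind(idx[ok], src[ok])] + k[t + r + 1]
    }
    B
  }
  v <- matrix(vol, d[1], d[2] * d[3])
  v <- bmat(d[1]) %*% v
  v <- array(v, d)
  v <- aperm(v, c(2, 1, 3))
  v <- matrix(v, d[2], d[1] * d[3])
  v <- bmat(d[2]) %*% v
  v <- aperm(array(v, c(d[2], d[1], d[3])), c(2, 1, 3))
  v <- matrix(aperm(v, c(3, 1, 2)), d[3], d[1] * d[2])
  v <- bmat(d[3]) %*% v
  aperm(array(v, c(d[3], d[1], d[2])), c(2, 3, 1))
}

# Trilinear sampling of vol at fractional 1-based voxel coordinates
# (matrix pts [n, 3]); out-of-bounds contributions are zero.
trilinearSample <- function(vol, pts) {
  d <- dim(vol)
  x0 <- floor(pts)
  f <- pts - x0
  acc <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- x0[, 1] + dx; iy <- x0[, 2] + dy; iz <- x0[, 3] + dz
    w <- (if (dx == 1) f[, 1] else 1 - f[, 1]) *
         (if (dy == 1) f[, 2] else 1 - f[, 2]) *
         (if (dz == 1) f[, 3] else 1 - f[, 3])
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3] &
          w > 0
    if (any(ok))
      acc[ok] <- acc[ok] + w[ok] * vol[cbind(ix[ok], iy[ok], iz[ok])]
  }
  acc
}

# --- tiny binary morphology on 3-D logical arrays (6-connectivity) ---------

shift3d <- function(m, dx, dy, dz) {
  d <- dim(m)
  out <- array(FALSE, d)
  xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[xs, ys, zs] <- m[xs - dx, ys - dy, zs - dz]
  out
}

dilate6 <- function(m, iter = 1L, dirs = "xyz") {
  sh <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  if (dirs == "xyz") sh <- c(sh, list(c(0, 0, 1), c(0, 0, -1)))
  for (i in seq_len(iter)) {
    acc <- m
    for (s in sh) acc <- acc | shift3d(m, s[1], s[2], s[3])
    m <- acc
  }
  m
}

erode6 <- function(m, iter = 1L, dirs = "xyz") !dilate6(!m, iter, dirs)

# Flood fill within `mask` starting from `seedMask`; in-plane only when
# dirs = "xy" (every z slice treated independently, vectorized together).
floodFill3d <- function(mask, seedMask, dirs = "xyz", maxIter = 512L) {
  reg <- seedMask & mask
  for (i in seq_len(maxIter)) {
    grown <- dilate6(reg, 1L, dirs) & mask
    if (!any(grown & !reg)) break
    reg <- grown
  }
  reg
}

# Border-connected background of a thresholded volume, per z-slice.
outsideRegion <- function(object3d) {
  d <- dim(object3d)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  floodFill3d(!object3d, border & !object3d, dirs = "xy")
}
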