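#' Reconstruction configuration
#'
#' @param nSubsets number of ordered subsets (must divide the view count)
#' @param nIterations number of full OSEM iterations
#' @param useAttenuation compensate attenuation using `muMap`?
#' @param muMap attenuation map on the reconstruction grid (required when
#'   `useAttenuation`)
#' @param useCdr model the collimator-detector response in the system matrix?
#' @param postfilter list with Butterworth `order` and `cutoffCm` (defaults
#'   order 5, cutoff 0.44 cm^-1)
#' @return A list of class `"ReconConfig"`.
#' @export
#' @examples
#' reconConfig(nSubsets = 4, nIterations = 5, useAttenuation = FALSE)
reconConfig <- function(nSubsets = 6L, nIterations = 10L,
                        useAttenuation = TRUE, muMap = NULL, useCdr = TRUE,
                        postfilter = list(order = 5, cutoffCm = 0.44)) {
  stopifnot(nSubsets >= 1, nIterations >= 1, postfilter$order >= 1,
            postfilter$cutoffCm > 0)
  if (useAttenuation && is.null(muMap))
    stop("useAttenuation requires a muMap")
  structure(list(nSubsets = as.integer(nSubsets),
                 nIterations = as.integer(nIterations),
                 useAttenuation = useAttenuation, muMap = muMap,
                 useCdr = useCdr, postfilter = postfilter),
            class = "ReconConfig")
}

# Bit-reversed ordering of 0..(n-1) (padded to the next power of two),
# the standard subset interleave that decorrelates consecutive subsets.
bitReversedOrder <- function(n) {
  bits <- ceiling(log2(max(n, 2)))
  rev <- vapply(0:(2^bits - 1), function(k) {
    r <- 0L
    for (b in seq_len(bits)) {
      r <- bitwOr(bitwShiftL(r, 1L), bitwAnd(k, 1L))
      k <- bitwShiftR(k, 1L)
    }
    r
  }, integer(1))
  rev[rev < n]
}

#' OSEM reconstruction
#'
#' Ordered-subsets expectation maximization with the module's matched
#' forward/back projectors. Multiplicative updates guarantee a nonnegative
#' estimate; voxels with zero subset sensitivity are excluded (never divided
#' by zero). With `nSubsets = 1` this is MLEM, whose Poisson log-likelihood
#' is non-decreasing for noiseless-consistent data.
#'
#' @param projections a [ProjectionSet-class] or a projection array
#'   `[bin, bin, view]` (photopeak window is reconstructed when a set is
#'   given)
#' @param geometry an [AcquisitionGeometry-class] (taken from the set when
#'   omitted)
#' @param config a [reconConfig()] list
#' @param window which window of a ProjectionSet to reconstruct
#' @param trackLoglik record the Poisson log-likelihood after each full
#'   iteration (costs one extra projection pass per iteration)?
#' @return Nonnegative 3-D activity estimate. With `trackLoglik` the
#'   attribute `"loglik"` stores the log-likelihood trace.
#' @export
osem <- function(projections, config = reconConfig(), geometry = NULL,
                 window = c("photopeak", "scatter"), trackLoglik = FALSE) {
  window <- match.arg(window)
  if (is(projections, "ProjectionSet")) {
    if (is.null(geometry)) geometry <- projections@geometry
    y <- slot(projections, window)
  } else y <- projections
  if (is.null(geometry)) stop("geometry required for raw projection arrays")
  if (geometry@nAngles %% config$nSubsets != 0)
    stop("nSubsets must divide the number of views")
  d <- c(geometry@detectorBins[1], geometry@detectorBins[1],
         geometry@detectorBins[2])
  mu <- if (config$useAttenuation) config$muMap else NULL
  if (!is.null(mu) && !identical(dim(mu), as.integer(d)))
    stop("muMap must live on the reconstruction grid")
  if (!identical(dim(y), as.integer(c(d[1], d[3], geometry@nAngles))))
    stop("projection shape inconsistent with geometry")
  sOrder <- bitReversedOrder(config$nSubsets) + 1L
  res <- cpp_osem(as.double(y),
                  as.double(if (is.null(mu)) array(0, d) else mu),
                  as.integer(d), viewAngles(geometry), geometry@binSize,
                  !is.null(mu), config$useCdr, geometry@cdrSigma0,
                  geometry@cdrSlope, geometry@orbitRadius,
                  config$nSubsets, config$nIterations, as.integer(sOrder),
                  trackLoglik, 1L)
  x <- res$x
  if (trackLoglik) attr(x, "loglik") <- res$loglik
  x
}

# Reconstruct several sinogram sets that share one system model (same
# geometry and attenuation map) in a single call; the cached rotation maps,
# attenuation factors and sensitivity images are reused across sets.
osemBatch <- function(ys, config, geometry) {
  if (geometry@nAngles %% config$nSubsets != 0)
    stop("nSubsets must divide the number of views")
  d <- c(geometry@detectorBins[1], geometry@detectorBins[1],
         geometry@detectorBins[2])
  mu <- if (config$useAttenuation) config$muMap else NULL
  if (!is.null(mu) && !identical(dim(mu), as.integer(d)))
    stop("muMap must live on the reconstruction grid")
  y <- array(unlist(ys, use.names = FALSE),
             c(d[1], d[3], geometry@nAngles, length(ys)))
  sOrder <- bitReversedOrder(config$nSubsets) + 1L
  res <- cpp_osem(as.double(y),
                  as.double(if (is.null(mu)) array(0, d) else mu),
                  as.integer(d), viewAngles(geometry), geometry@binSize,
                  !is.null(mu), config$useCdr, geometry@cdrSigma0,
                  geometry@cdrSlope, geometry@orbitRadius,
                  config$nSubsets, config$nIterations, as.integer(sOrder),
                  FALSE, length(ys))
  res$xs
}

#' Reconstruct the initial scatter-window and photopeak estimates
#'
#' Both energy windows are reconstructed without attenuation compensation
#' (the transmission-less starting point: the scatter-window reconstruction
#' is the initial estimate of the attenuation map, the photopeak
#' reconstruction the initial activity estimate). Each volume is
#' intensity-normalized to unit mean over its nonzero support, the
#' normalization assumed by the segmentation stage.
#'
#' @param projections a [ProjectionSet-class] carrying both windows
#' @param scatterConfig,photoConfig [reconConfig()] lists (attenuation is
#'   forced off)
#' @return List with elements `scatter` and `photopeak`.
#' @export
reconstructInitialEstimates <- function(projections,
    scatterConfig = reconConfig(nSubsets = 4, nIterations = 5,
                                useAttenuation = FALSE),
    photoConfig = reconConfig(nSubsets = 6, nIterations = 10,
                              useAttenuation = FALSE)) {
  stopifnot(is(projections, "ProjectionSet"))
  if (!length(projections@scatter))
    stop("projection set carries no scatter window")
  scatterConfig$useAttenuation <- FALSE
  photoConfig$useAttenuation <- FALSE
  normUnit <- function(v) {
    s <- mean(v[v > 0])
    if (is.finite(s) && s > 0) v / s else v
  }
  list(scatter = normUnit(osem(projections, scatterConfig,
                               window = "scatter")),
       photopeak = normUnit(osem(projections, photoConfig,
                                 window = "photopeak")))
}

#' 3-D Butterworth low-pass filter
#'
#' Radially symmetric frequency-domain gain
#' `1 / sqrt(1 + (nu / cutoff)^(2 * order))`, applied by FFT; the output is
#' real. DC gain is exactly 1 and the gain at the cutoff frequency is
#' exactly `1/sqrt(2)`.
#'
#' @param volume 3-D array
#' @param order filter order (default 5)
#' @param cutoffCm cutoff frequency in cm^-1 (default 0.44)
#' @param voxelSize voxel size in cm
#' @return Filtered volume.
#' @export
butterworthFilter <- function(volume, order = 5, cutoffCm = 0.44,
                              voxelSize = 0.68) {
  d <- dim(volume)
  nyq <- 1 / (2 * voxelSize)
  if (cutoffCm >= nyq) {
    warning("cutoff at or above Nyquist (", signif(nyq, 4),
            " cm^-1); clamping")
    cutoffCm <- nyq
  }
  f1 <- fftFreq(d[1]) / voxelSize
  f2 <- fftFreq(d[2]) / voxelSize
  f3 <- fftFreq(d[3]) / voxelSize
  r2 <- outer(outer(f1^2, f2^2, `+`), f3^2, `+`)
  gain <- 1 / sqrt(1 + (sqrt(r2) / cutoffCm)^(2 * order))
  Re(fft(fft(volume) * gain, inverse = TRUE)) / prod(d)
}

#' Butterworth gain at a given frequency
#'
#' Closed-form gain of the filter used by [butterworthFilter()].
#'
#' @param nu frequency in cm^-1
#' @param order filter order
#' @param cutoffCm cutoff frequency in cm^-1
#' @return Gain in (0, 1].
#' @export
butterworthGain <- function(nu, order = 5, cutoffCm = 0.44)
  1 / sqrt(1 + (nu / cutoffCm)^(2 * order))

#' Reorient a volume into short-axis slices
#'
#' Rigid rotation about the heart center that aligns the LV long axis with
#' the slice normal (output z axis), with trilinear resampling on the same
#' grid. When the long axis already equals the grid z axis the map is the
#' identity.
#'
#' @param volume 3-D array
#' @param heart a [HeartGeometry-class]
#' @param voxelSize voxel size in cm
#' @return Short-axis volume, same shape.
#' @export
reorientShortAxis <- function(volume, heart, voxelSize = 0.68) {
  if (sqrt(sum(heart@axis^2)) < 1e-8) stop("degenerate long axis")
  d <- dim(volume)
  M <- shortAxisRotation(heart)
  x <- axisCoords(d[1], voxelSize); y <- axisCoords(d[2], voxelSize)
  z <- axisCoords(d[3], voxelSize)
  P <- cbind(rep(x, times = d[2] * d[3]),
             rep(rep(y, each = d[1]), times = d[3]),
             rep(z, each = d[1] * d[2]))
  c0 <- heart@center
  src <- sweep(sweep(P, 2, c0) %*% t(M), 2, c0, `+`)
  # world (cm) -> 1-based voxel coordinates
  vx <- sweep(sweep(src, 2, c(x[1], y[1], z[1])), 2,
              rep(voxelSize, 3), `/`) + 1
  array(trilinearSample(volume, vx), d)
}

# Rotation whose columns map output (short-axis) axes to world axes:
# output z -> the LV long axis. Proper rotation (det +1).
shortAxisRotation <- function(heart) {
  w <- heart@axis / sqrt(sum(heart@axis^2))
  u <- c(1, 0, 0) - sum(c(1, 0, 0) * w) * w
  if (sqrt(sum(u^2)) < 1e-6) u <- c(0, 1, 0) - sum(c(0, 1, 0) * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  cbind(u, v, w)
}

#' Map a world point into short-axis voxel coordinates
#'
#' Gives the (fractional, 1-based) voxel position that a world-coordinate
#' point occupies in the output of [reorientShortAxis()]; used to place the
#' observer ROI at the defect centroid.
#'
#' @param point numeric(3) world coordinates (cm)
#' @param heart a [HeartGeometry-class]
#' @param shape integer(3) volume shape
#' @param voxelSize voxel size in cm
#' @return numeric(3) voxel coordinates.
#' @export
shortAxisCoords <- function(point, heart, shape, voxelSize = 0.68) {
  M <- shortAxisRotation(heart)
  c0 <- heart@center
  pOut <- c0 + as.vector(t(M) %*% (point - c0))
  (pOut / voxelSize) + (shape - 1) / 2 + 1
}

#' Extract the observer region of interest
#'
#' 32x32 crop from the short-axis slice containing the defect centroid, with
#' the centroid at pixel (16, 16) in 0-based indexing. Crops that exceed the
#' volume are zero-padded with a warning.
#'
#' @param shortAxisVolume output of [reorientShortAxis()]
#' @param centroidVoxel numeric(3) voxel coordinates (1-based, possibly
#'   fractional) of the defect centroid in the short-axis volume
#' @param size ROI side in pixels (default 32)
#' @return `size x size` numeric matrix.
#' @export
extractROI <- function(shortAxisVolume, centroidVoxel, size = 32L) {
  d <- dim(shortAxisVolume)
  k <- round(centroidVoxel[3])
  if (k < 1 || k > d[3]) stop("centroid outside the volume")
  i0 <- round(centroidVoxel[1]); j0 <- round(centroidVoxel[2])
  half <- size %/% 2
  ri <- (i0 - half):(i0 + half - 1)
  rj <- (j0 - half):(j0 + half - 1)
  out <- matrix(0, size, size)
  oki <- ri >= 1 & ri <= d[1]; okj <- rj >= 1 & rj <= d[2]
  if (!all(oki) || !all(okj)) warning("ROI exceeds volume bounds; zero-padded")
  out[which(oki), which(okj)] <- shortAxisVolume[ri[oki], rj[okj], k]
  out
}

# Precompute the trilinear gather (indices and weights) of the short-axis
# resampling for one heart geometry, returning a fast closure; used by the
# experiment driver, which reorients many volumes per patient.
makeShortAxisResampler <- function(heart, shape, voxelSize) {
  d <- as.integer(shape)
  M <- shortAxisRotation(heart)
  x <- axisCoords(d[1], voxelSize); y <- axisCoords(d[2], voxelSize)
  z <- axisCoords(d[3], voxelSize)
  P <- cbind(rep(x, times = d[2] * d[3]),
             rep(rep(y, each = d[1]), times = d[3]),
             rep(z, each = d[1] * d[2]))
  src <- sweep(sweep(P, 2, heart@center) %*% t(M), 2, heart@center, `+`)
  vx <- sweep(sweep(src, 2, c(x[1], y[1], z[1])), 2,
              rep(voxelSize, 3), `/`) + 1
  x0 <- floor(vx); f <- vx - x0
  idx <- vector("list", 8); wt <- vector("list", 8)
  k <- 0L
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    k <- k + 1L
    ix <- x0[, 1] + dx; iy <- x0[, 2] + dy; iz <- x0[, 3] + dz
    w <- (if (dx == 1) f[, 1] else 1 - f[, 1]) *
         (if (dy == 1) f[, 2] else 1 - f[, 2]) *
         (if (dz == 1) f[, 3] else 1 - f[, 3])
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
    w[!ok] <- 0
    lin <- ix + (iy - 1) * d[1] + (iz - 1) * d[1] * d[2]
    lin[!ok] <- 1L
    idx[[k]] <- as.integer(lin); wt[[k]] <- w
  }
  function(vol) {
    acc <- wt[[1]] * vol[idx[[1]]]
    for (k in 2:8) acc <- acc + wt[[k]] * vol[idx[[k]]]
    array(acc, d)
  }
}
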