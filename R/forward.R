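#' View angles of an acquisition
#'
#' @param geometry an [AcquisitionGeometry-class]
#' @return numeric vector of view angles in radians, equispaced over the arc.
#' @export
viewAngles <- function(geometry) {
  n <- geometry@nAngles
  (geometry@angularRange * pi / 180) * (seq_len(n) - 1) / n
}

checkGridVsGeometry <- function(vol, geometry) {
  d <- dim(vol)
  if (length(d) != 3L)
    stop("expected a 3-D volume")
  if (d[1] != geometry@detectorBins[1] || d[3] != geometry@detectorBins[2])
    stop("volume transaxial/axial extent must match the detector bins")
  invisible(d)
}

#' Attenuated forward projection with collimator-detector response
#'
#' Rotation-based parallel-beam projector: for each view the volume is
#' rotated about the scanner axis (bilinear interpolation), attenuated by
#' `exp(-integral of mu)` from each voxel to the detector, blurred in-plane by
#' a depth-dependent Gaussian (sigma = `cdrSigma0 + cdrSlope * depth`), and
#' summed along the detector normal. Linear in `activity`.
#'
#' @param activity nonnegative 3-D array (uptake units)
#' @param mu attenuation map (cm^-1) on the same grid, or `NULL` to disable
#'   attenuation modelling
#' @param geometry an [AcquisitionGeometry-class]
#' @param useCdr model the collimator-detector response?
#' @param voxelSize voxel size in cm (defaults to the detector bin size)
#' @return Array `[transaxial bin, axial bin, view]` of expected counts.
#' @export
forwardProject <- function(activity, mu = NULL, geometry = acquisitionGeometry(),
                           useCdr = TRUE, voxelSize = geometry@binSize) {
  d <- checkGridVsGeometry(activity, geometry)
  useAtt <- !is.null(mu)
  if (useAtt) {
    if (!identical(dim(mu), dim(activity)))
      stop("activity and mu must share a grid")
    if (any(mu < 0)) stop("mu must be nonnegative")
  } else mu <- array(0, d)
  cpp_project(as.double(activity), as.double(mu), as.integer(d),
              viewAngles(geometry), voxelSize, useAtt, useCdr,
              geometry@cdrSigma0, geometry@cdrSlope, geometry@orbitRadius)
}

#' Adjoint of the forward projector
#'
#' Exact matrix transpose of [forwardProject()] under the standard Euclidean
#' inner products, as required for EM-type reconstruction.
#'
#' @param views array `[transaxial bin, axial bin, view]`
#' @param mu attenuation map or `NULL`
#' @param geometry an [AcquisitionGeometry-class]
#' @param useCdr model the collimator-detector response?
#' @param voxelSize voxel size in cm
#' @return 3-D volume.
#' @export
backProject <- function(views, mu = NULL, geometry = acquisitionGeometry(),
                        useCdr = TRUE, voxelSize = geometry@binSize) {
  d <- dim(views)
  if (length(d) != 3L || d[3] != geometry@nAngles ||
      d[1] != geometry@detectorBins[1] || d[2] != geometry@detectorBins[2])
    stop("projection shape inconsistent with geometry")
  vdim <- c(geometry@detectorBins[1], geometry@detectorBins[1],
            geometry@detectorBins[2])
  useAtt <- !is.null(mu)
  if (useAtt) {
    if (!identical(dim(mu), as.integer(vdim)))
      stop("mu shape inconsistent with geometry")
  } else mu <- array(0, vdim)
  cpp_backproject(as.double(views), as.double(mu), as.integer(vdim),
                  viewAngles(geometry), voxelSize, useAtt, useCdr,
                  geometry@cdrSigma0, geometry@cdrSlope,
                  geometry@orbitRadius)
}

#' Expected scatter-window projections
#'
#' Phenomenological effective-scatter-source model: the probability of
#' scatter at a location is proportional to the attenuation there, weighted
#' by the photon flux traversing it. The flux surrogate is the activity
#' convolved with a broad Gaussian kernel plus a diffuse component
#' (`diffuse` times its in-support mean, standing in for the pervasive
#' multiply-scattered pool); the effective source is this flux modulated
#' voxelwise by `mu / muWater`. It is forward projected with broad-beam
#' attenuation (`buildup * mu`; scattered photons experience less than the
#' narrow-beam coefficient because of buildup), and globally scaled so that
#' total scatter counts equal `fraction` times the total primary counts.
#' Reconstructions of this channel show body/lung/background attenuation
#' contrast, the premise of transmission-less attenuation estimation.
#'
#' @param activity 3-D activity array
#' @param mu attenuation map (cm^-1)
#' @param geometry an [AcquisitionGeometry-class]
#' @param fraction scatter-to-primary count fraction (default 0.3)
#' @param kernelFwhm scatter kernel FWHM in cm (default 6)
#' @param diffuse diffuse-flux fraction (default 1.5; the multiply-
#'   scattered pool exceeds the local single-scatter term in this window)
#' @param buildup broad-beam attenuation factor for the scatter channel
#'   (default 0.4)
#' @param muWater water attenuation coefficient used for the modulation
#' @param voxelSize voxel size in cm
#' @param primary optional precomputed photopeak expectation (saves one
#'   projection pass)
#' @return Array of expected scatter-window counts, same shape as the
#'   photopeak projections.
#' @export
simulateScatter <- function(activity, mu, geometry = acquisitionGeometry(),
                            fraction = 0.3, kernelFwhm = 6, diffuse = 1.5,
                            buildup = 0.4, muWater = 0.1537,
                            voxelSize = geometry@binSize, primary = NULL) {
  if (fraction < 0) stop("scatter fraction must be >= 0")
  if (!identical(dim(activity), dim(mu)))
    stop("activity and mu must share a grid")
  if (is.null(primary))
    primary <- forwardProject(activity, mu, geometry, voxelSize = voxelSize)
  sigmaVox <- kernelFwhm / (2 * sqrt(2 * log(2))) / voxelSize
  flux <- gaussSmooth3d(activity, sigmaVox)
  supp <- mu > 0
  if (any(supp)) flux <- flux + diffuse * mean(flux[supp]) * supp
  src <- flux * (mu / muWater)
  proj <- forwardProject(src, buildup * mu, geometry, voxelSize = voxelSize)
  tot <- sum(proj)
  if (tot == 0 || sum(activity) == 0) return(array(0, dim(proj)))
  proj * (fraction * sum(primary) / tot)
}

#' Simulate a noiseless ProjectionSet for a phantom
#'
#' Convenience wrapper producing paired photopeak and scatter-window
#' expectations for one phantom.
#'
#' @param phantom a [PhantomInstance-class]
#' @param geometry an [AcquisitionGeometry-class]
#' @param scatterFraction,kernelFwhm scatter-model parameters
#' @return A [ProjectionSet-class] with `isNoisy = FALSE`.
#' @export
projectPhantom <- function(phantom, geometry = acquisitionGeometry(),
                           scatterFraction = 0.3, kernelFwhm = 6) {
  vox <- phantom@grid@voxelSize
  pk <- forwardProject(phantom@activity, phantom@mu, geometry,
                       voxelSize = vox)
  sc <- simulateScatter(phantom@activity, phantom@mu, geometry,
                        fraction = scatterFraction, kernelFwhm = kernelFwhm,
                        voxelSize = vox, primary = pk)
  projectionSet(geometry, pk, sc)
}

#' Apply Poisson counting noise to a projection set
#'
#' The photopeak expectation is scaled so its total equals `totalCounts`
#' (the scatter window is scaled by the same factor, preserving the
#' scatter-to-primary fraction), then every bin is replaced by an
#' independent Poisson draw. Reproducible per seed.
#'
#' @param projections a [ProjectionSet-class]
#' @param totalCounts target total photopeak counts (> 0)
#' @param seed integer seed
#' @return A noisy [ProjectionSet-class].
#' @export
addPoissonNoise <- function(projections, totalCounts = 4e6, seed = 1) {
  stopifnot(is(projections, "ProjectionSet"))
  if (totalCounts <= 0) stop("totalCounts must be > 0")
  pk <- projections@photopeak
  if (any(pk < 0) || any(projections@scatter < 0))
    stop("negative expectations")
  s <- totalCounts / sum(pk)
  withSeed(seed, {
    pk2 <- array(rpois(length(pk), s * pk), dim(pk))
    sc2 <- array(rpois(length(projections@scatter), s * projections@scatter),
                 dim(projections@scatter))
  })
  new("ProjectionSet", geometry = projections@geometry,
      photopeak = pk2 * 1.0, scatter = sc2 * 1.0,
      windowBounds = projections@windowBounds, isNoisy = TRUE)
}
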