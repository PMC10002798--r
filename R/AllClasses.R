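#' @useDynLib slacspect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats fft kmeans optim pnorm qnorm quantile rnorm rpois runif
#'   sd cor
NULL

#' Tissue class encoding
#'
#' Integer labels used throughout the package for the six-class tissue
#' segmentation: 0 background, 1 skin/subcutaneous adipose, 2 muscles and
#' organs, 3 lungs, 4 bones, 5 patient table.
#'
#' @return Named integer vector mapping class name to label.
#' @export
#' @examples
#' tissueClasses()
tissueClasses <- function() {
  c(background = 0L, skin_adipose = 1L, soft_tissue = 2L,
    lungs = 3L, bones = 4L, table = 5L)
}

#' VolumeGrid: reconstruction/simulation grid
#'
#' @slot shape integer(3), voxels per axis (each >= 8)
#' @slot voxelSize numeric(1), isotropic voxel size in cm
#' @export
setClass("VolumeGrid",
  representation(shape = "integer", voxelSize = "numeric"),
  prototype(shape = c(64L, 64L, 64L), voxelSize = 0.68))

setValidity("VolumeGrid", function(object) {
  if (length(object@shape) != 3L) return("shape must have length 3")
  if (any(object@shape < 8L)) return("all shape entries must be >= 8")
  if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
    return("voxelSize must be a single positive number")
  TRUE
})

#' Construct a VolumeGrid
#'
#' @param shape integer(3) voxel counts; default `c(64, 64, 64)`
#' @param voxelSize voxel size in cm; default 0.68
#' @return A [VolumeGrid-class] object.
#' @export
#' @examples
#' volumeGrid(c(32, 32, 32), 1.36)
volumeGrid <- function(shape = c(64L, 64L, 64L), voxelSize = 0.68) {
  new("VolumeGrid", shape = as.integer(shape), voxelSize = voxelSize)
}

#' HeartGeometry: parametric left-ventricular shell
#'
#' The LV myocardium is modelled as a half-ellipsoidal shell: the region
#' between an outer and an inner half-ellipsoid of revolution about the long
#' axis, open at the base. Circumferential position is measured in the
#' short-axis plane about the long axis; wall reference angles default to
#' lateral 0, anterior 90, inferior 270 degrees.
#'
#' @slot center numeric(3), world coordinates (cm, origin at grid center)
#' @slot axis numeric(3), unit vector from base towards apex
#' @slot outerRadius,innerRadius transverse semi-axes in cm (inner < outer)
#' @slot outerLength,innerLength axial semi-lengths in cm
#' @slot wallAngles named numeric, wall name -> reference angle (degrees)
#' @export
setClass("HeartGeometry",
  representation(center = "numeric", axis = "numeric",
    outerRadius = "numeric", innerRadius = "numeric",
    outerLength = "numeric", innerLength = "numeric",
    wallAngles = "numeric"))

setValidity("HeartGeometry", function(object) {
  if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-8)
    return("axis must have unit norm")
  if (object@innerRadius >= object@outerRadius)
    return("innerRadius must be smaller than outerRadius")
  if (!all(c("anterior", "inferior", "lateral") %in% names(object@wallAngles)))
    return("wallAngles must name anterior, inferior and lateral")
  TRUE
})

#' Construct a HeartGeometry
#'
#' @param center world coordinates of the LV base center (cm)
#' @param axis unit long-axis direction (base towards apex)
#' @param outerRadius,innerRadius transverse shell radii (cm)
#' @param outerLength,innerLength axial semi-lengths (cm)
#' @param wallAngles named reference angles in degrees
#' @return A [HeartGeometry-class] object.
#' @export
heartGeometry <- function(center, axis, outerRadius = 3.5, innerRadius = 2.0,
                          outerLength = 7.5, innerLength = 6.0,
                          wallAngles = c(lateral = 0, anterior = 90,
                                         inferior = 270)) {
  axis <- axis / sqrt(sum(axis^2))
  new("HeartGeometry", center = as.numeric(center), axis = as.numeric(axis),
      outerRadius = outerRadius, innerRadius = innerRadius,
      outerLength = outerLength, innerLength = innerLength,
      wallAngles = wallAngles)
}

#' DefectSpec: a parametric perfusion defect
#'
#' A defect is the triple (circumferential extent, severity, wall). The
#' catalog grid is extents \{30, 60, 90\} degrees, severities
#' \{0.10, 0.25, 0.50\} (fractional activity reduction), walls
#' \{anterior, inferior, lateral\}. Severity 0 is additionally accepted as a
#' degenerate no-op, useful for controls.
#'
#' @slot extentDeg numeric(1) circumferential extent in degrees
#' @slot severity numeric(1) fractional reduction of myocardial activity
#' @slot wall character(1) wall name
#' @export
setClass("DefectSpec",
  representation(extentDeg = "numeric", severity = "numeric",
                 wall = "character"))

setValidity("DefectSpec", function(object) {
  if (!object@extentDeg %in% c(30, 60, 90))
    return("extentDeg must be one of 30, 60, 90")
  if (!object@severity %in% c(0, 0.10, 0.25, 0.50))
    return("severity must be one of 0, 0.10, 0.25, 0.50")
  if (!object@wall %in% c("anterior", "inferior", "lateral"))
    return("wall must be anterior, inferior or lateral")
  TRUE
})

#' Construct a DefectSpec
#'
#' @param extentDeg extent in degrees (30, 60 or 90)
#' @param severity fractional activity reduction (0.10, 0.25, 0.50; 0 allowed
#'   as a degenerate control)
#' @param wall one of "anterior", "inferior", "lateral"
#' @return A [DefectSpec-class] object.
#' @export
#' @examples
#' defectSpec(60, 0.25, "inferior")
defectSpec <- function(extentDeg, severity, wall) {
  new("DefectSpec", extentDeg = as.numeric(extentDeg),
      severity = as.numeric(severity), wall = as.character(wall))
}

#' PhantomInstance: one synthetic thorax
#'
#' Holds co-registered activity (arbitrary uptake units), attenuation
#' (cm^-1 at 140 keV), and six-class label volumes on a common grid, plus the
#' LV geometry and the generating seed. Activity is zero outside the body
#' (background and table carry no tracer).
#'
#' @slot grid a [VolumeGrid-class]
#' @slot activity,mu numeric 3-D arrays
#' @slot labels integer 3-D array with values in 0..5
#' @slot heart a [HeartGeometry-class]
#' @slot classMu named numeric(6), the per-class attenuation coefficients
#'   realized for this phantom (nominal values with per-phantom jitter)
#' @slot seed integer generating seed
#' @slot params list of anatomy parameters used
#' @export
setClass("PhantomInstance",
  representation(grid = "VolumeGrid", activity = "array", mu = "array",
    labels = "array", heart = "HeartGeometry", classMu = "numeric",
    seed = "integer", params = "list"))

setValidity("PhantomInstance", function(object) {
  if (!identical(dim(object@activity), dim(object@mu)) ||
      !identical(dim(object@activity), dim(object@labels)))
    return("activity, mu and labels must share a shape")
  if (!identical(dim(object@activity), as.integer(object@grid@shape)))
    return("volume shape must match the grid")
  if (any(object@activity < 0)) return("activity must be nonnegative")
  if (any(object@mu < 0) || any(object@mu > 0.5))
    return("mu must lie in [0, 0.5] cm^-1")
  if (!all(sort(unique(as.vector(object@labels))) == 0:5))
    return("labels must cover exactly the six classes 0..5")
  bg <- object@labels == tissueClasses()["background"] |
        object@labels == tissueClasses()["table"]
  if (any(object@activity[bg] != 0))
    return("activity outside the body must be zero")
  TRUE
})

#' AcquisitionGeometry: parallel-beam SPECT system description
#'
#' @slot nAngles number of projection views
#' @slot angularRange arc covered, degrees (default 180)
#' @slot detectorBins integer(2), transaxial x axial bins
#' @slot binSize detector bin size in cm (equal to the voxel size)
#' @slot cdrSigma0 intrinsic collimator-detector blur sigma (cm)
#' @slot cdrSlope blur sigma growth per cm of depth
#' @slot orbitRadius detector orbit radius (cm)
#' @export
setClass("AcquisitionGeometry",
  representation(nAngles = "integer", angularRange = "numeric",
    detectorBins = "integer", binSize = "numeric", cdrSigma0 = "numeric",
    cdrSlope = "numeric", orbitRadius = "numeric"))

setValidity("AcquisitionGeometry", function(object) {
  if (object@nAngles < 4L) return("nAngles must be >= 4")
  if (object@binSize <= 0) return("binSize must be positive")
  if (object@cdrSlope < 0) return("cdrSlope must be >= 0")
  TRUE
})

#' Construct an AcquisitionGeometry
#'
#' Defaults describe a standard myocardial-perfusion acquisition: 60 views
#' over a 180-degree arc, 64x64 bins at 0.68 cm, and a depth-dependent
#' Gaussian collimator-detector response.
#'
#' @param nAngles number of views
#' @param angularRange arc in degrees
#' @param detectorBins integer(2) detector bins
#' @param binSize bin size (cm)
#' @param cdrSigma0 intrinsic blur sigma (cm)
#' @param cdrSlope blur sigma slope per cm depth
#' @param orbitRadius orbit radius (cm)
#' @return An [AcquisitionGeometry-class] object.
#' @export
#' @examples
#' acquisitionGeometry(nAngles = 48)
acquisitionGeometry <- function(nAngles = 60L, angularRange = 180,
                                detectorBins = c(64L, 64L), binSize = 0.68,
                                cdrSigma0 = 0.35, cdrSlope = 0.018,
                                orbitRadius = 25) {
  new("AcquisitionGeometry", nAngles = as.integer(nAngles),
      angularRange = angularRange, detectorBins = as.integer(detectorBins),
      binSize = binSize, cdrSigma0 = cdrSigma0, cdrSlope = cdrSlope,
      orbitRadius = orbitRadius)
}

#' ProjectionSet: paired photopeak and scatter-window data
#'
#' Projection arrays are stored `[transaxial bin, axial bin, view]`. The
#' energy-window bounds default to photopeak 126-154 keV and scatter
#' 114-126 keV.
#'
#' @slot geometry an [AcquisitionGeometry-class]
#' @slot photopeak,scatter nonnegative numeric arrays
#' @slot windowBounds list with numeric(2) entries `photopeak`, `scatter` (keV)
#' @slot isNoisy logical, whether Poisson noise has been applied
#' @export
setClass("ProjectionSet",
  representation(geometry = "AcquisitionGeometry", photopeak = "array",
    scatter = "array", windowBounds = "list", isNoisy = "logical"))

setValidity("ProjectionSet", function(object) {
  g <- object@geometry
  want <- c(g@detectorBins[1], g@detectorBins[2], g@nAngles)
  if (!identical(dim(object@photopeak), as.integer(want)))
    return("photopeak shape inconsistent with geometry")
  if (length(object@scatter) &&
      !identical(dim(object@scatter), dim(object@photopeak)))
    return("scatter shape must match photopeak")
  if (any(object@photopeak < 0) || (length(object@scatter) &&
      any(object@scatter < 0)))
    return("projection arrays must be nonnegative")
  TRUE
})

#' Construct a ProjectionSet
#'
#' @param geometry an [AcquisitionGeometry-class]
#' @param photopeak,scatter projection arrays `[bin, bin, view]`
#' @param windowBounds energy-window bounds in keV
#' @param isNoisy whether the data are Poisson realizations
#' @return A [ProjectionSet-class] object.
#' @export
projectionSet <- function(geometry, photopeak, scatter = array(0, dim(photopeak)),
                          windowBounds = list(photopeak = c(126, 154),
                                              scatter = c(114, 126)),
                          isNoisy = FALSE) {
  new("ProjectionSet", geometry = geometry, photopeak = photopeak,
      scatter = scatter, windowBounds = windowBounds, isNoisy = isNoisy)
}

#' TissueModel: class-wise predefined attenuation coefficients
#'
#' Mean attenuation coefficient (cm^-1 at 140 keV) per tissue class,
#' estimated from training attenuation maps and their segmentations.
#'
#' @slot classMu numeric(6) named "0".."5"
#' @slot provenance free-text identifier of the training set
#' @export
setClass("TissueModel",
  representation(classMu = "numeric", provenance = "character"))

setValidity("TissueModel", function(object) {
  if (length(object@classMu) != 6L ||
      !identical(names(object@classMu), as.character(0:5)))
    return("classMu must be a numeric(6) named '0'..'5'")
  if (any(object@classMu < 0) || any(object@classMu > 0.5))
    return("coefficients must lie in [0, 0.5]")
  if (object@classMu[["0"]] != 0)
    return("background coefficient must be 0")
  TRUE
})

#' BilinearModel: piecewise-linear HU to attenuation conversion
#'
#' Continuous piecewise-linear map with mu(-1000 HU) = 0 and
#' mu(0 HU) = muWater; the soft-tissue branch slope is therefore
#' muWater/1000 per HU, and the bone branch slope is free.
#'
#' @slot muWater attenuation of water at 140 keV (cm^-1)
#' @slot boneSlope slope for HU > 0 (cm^-1 per HU)
#' @export
setClass("BilinearModel",
  representation(muWater = "numeric", boneSlope = "numeric"))

setValidity("BilinearModel", function(object) {
  if (object@muWater <= 0) return("muWater must be positive")
  if (object@boneSlope < 0) return("boneSlope must be nonnegative")
  TRUE
})

#' Construct a BilinearModel
#'
#' Defaults: muWater = 0.1537 cm^-1 at 140 keV; bone slope chosen so that
#' 1000 HU maps to 0.25 cm^-1.
#'
#' @param muWater water attenuation coefficient (cm^-1)
#' @param boneSlope bone-branch slope (cm^-1 per HU)
#' @return A [BilinearModel-class] object.
#' @export
#' @examples
#' bilinearModel()
bilinearModel <- function(muWater = 0.1537,
                          boneSlope = (0.25 - 0.1537) / 1000) {
  new("BilinearModel", muWater = muWater, boneSlope = boneSlope)
}

#' ChannelBank: rotationally symmetric frequency channels
#'
#' @slot imageSize side of the square ROI (pixels)
#' @slot edges matrix `[nChannels, 2]` of band edges (cycles/pixel)
#' @slot channels matrix `[imageSize^2, nChannels]`, unit-norm columns
#' @export
setClass("ChannelBank",
  representation(imageSize = "integer", edges = "matrix",
                 channels = "matrix"))

setValidity("ChannelBank", function(object) {
  if (ncol(object@edges) != 2L) return("edges must be an [n, 2] matrix")
  nrm <- sqrt(colSums(object@channels^2))
  if (any(abs(nrm - 1) > 1e-8)) return("channel columns must have unit norm")
  TRUE
})

#' ObserverStudyResult: one arm's observer study
#'
#' @slot statistics per-image CHO test statistics
#' @slot labels integer 0/1 truth (1 = defect present)
#' @slot roc data.frame with columns fpf, tpf (empirical ROC)
#' @slot auc empirical AUC (Mann-Whitney, ties 0.5)
#' @slot aucCI numeric(2) bootstrap 95% CI
#' @slot binormal list with elements a, b, auc, converged
#' @slot method arm tag ("SLAC", "CTAC" or "NAC")
#' @export
setClass("ObserverStudyResult",
  representation(statistics = "numeric", labels = "integer",
    roc = "data.frame", auc = "numeric", aucCI = "numeric",
    binormal = "list", method = "character"))

setValidity("ObserverStudyResult", function(object) {
  if (length(object@statistics) != length(object@labels))
    return("one statistic per image required")
  if (length(object@aucCI) == 2L && !anyNA(object@aucCI) &&
      (object@aucCI[1] > object@auc + 1e-12 ||
       object@aucCI[2] < object@auc - 1e-12))
    return("CI must bracket the AUC")
  TRUE
})
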