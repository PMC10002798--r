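#' @export
setMethod("show", "VolumeGrid", function(object) {
  cat(sprintf("VolumeGrid: %s voxels at %.3g cm (%.3g cm field of view)\n",
              paste(object@shape, collapse = "x"), object@voxelSize,
              object@shape[1] * object@voxelSize))
})

#' @export
setMethod("show", "PhantomInstance", function(object) {
  tb <- table(factor(object@labels, levels = 0:5,
                     labels = names(tissueClasses())))
  cat(sprintf("PhantomInstance (seed %d): %s voxels at %.3g cm\n",
              object@seed, paste(object@grid@shape, collapse = "x"),
              object@grid@voxelSize))
  cat("  class volumes (voxels):",
      paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  cat(sprintf("  myocardial uptake ratio %.2f; mu range [%.3g, %.3g] cm^-1\n",
              max(object@activity) / stats::median(
                object@activity[object@labels == 2L]),
              min(object@mu), max(object@mu)))
})

#' @export
setMethod("show", "DefectSpec", function(object) {
  cat(sprintf("DefectSpec: %s wall, %g deg extent, %.0f%% severity\n",
              object@wall, object@extentDeg, 100 * object@severity))
})

#' @export
setMethod("show", "AcquisitionGeometry", function(object) {
  cat(sprintf(
    "AcquisitionGeometry: %d views / %g deg, %dx%d bins at %.3g cm\n",
    object@nAngles, object@angularRange, object@detectorBins[1],
    object@detectorBins[2], object@binSize))
  cat(sprintf("  CDR sigma %.3g + %.3g * depth cm; orbit %.3g cm\n",
              object@cdrSigma0, object@cdrSlope, object@orbitRadius))
})

#' @export
setMethod("show", "ProjectionSet", function(object) {
  cat(sprintf(
    "ProjectionSet (%s): %d views, photopeak %g counts, scatter %g\n",
    if (object@isNoisy) "noisy" else "noiseless", object@geometry@nAngles,
    sum(object@photopeak), sum(object@scatter)))
})

#' @export
setMethod("show", "TissueModel", function(object) {
  cat("TissueModel (", object@provenance, "), mu in cm^-1:\n", sep = "")
  for (cl in 0:5)
    cat(sprintf("  %-13s %.4f\n", names(tissueClasses())[cl + 1],
                object@classMu[[as.character(cl)]]))
})

#' @export
setMethod("show", "ChannelBank", function(object) {
  cat(sprintf(
    "ChannelBank: %d rotationally symmetric octave channels on %dx%d\n",
    ncol(object@channels), object@imageSize, object@imageSize))
})

#' @export
setMethod("show", "ObserverStudyResult", function(object) {
  cat(sprintf("ObserverStudyResult [%s]: %d images (%d present)\n",
              object@method, length(object@labels), sum(object@labels)))
  cat(sprintf("  empirical AUC %.3f [%.3f, %.3f]", object@auc,
              object@aucCI[1], object@aucCI[2]))
  if (isTRUE(object@binormal$converged))
    cat(sprintf("; binormal a=%.2f b=%.2f AUC %.3f", object@binormal$a,
                object@binormal$b, object@binormal$auc))
  cat("\n")
})
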