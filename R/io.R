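#' Write a volume as NIfTI-1
#'
#' @param volume 3-D array
#' @param path output `.nii` / `.nii.gz` path
#' @param voxelSize voxel size in cm (stored as mm in the header)
#' @return The path, invisibly.
#' @export
writeVolume <- function(volume, path, voxelSize = 0.68) {
  img <- RNifti::asNifti(volume, pixdim = rep(voxelSize * 10, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path input path
#' @return 3-D array with attribute `"voxelSize"` (cm).
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxelSize") <- RNifti::pixdim(img)[1] / 10
  out
}

#' Write a phantom to disk
#'
#' Activity, attenuation and label volumes as NIfTI-1 plus a YAML sidecar
#' with seed, class coefficients and heart geometry.
#'
#' @param phantom a [PhantomInstance-class]
#' @param dir output directory (created if needed)
#' @param name file stem
#' @return The sidecar path, invisibly.
#' @export
writePhantom <- function(phantom, dir, name = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vox <- phantom@grid@voxelSize
  writeVolume(phantom@activity, file.path(dir, paste0(name, "_activity.nii.gz")), vox)
  writeVolume(phantom@mu, file.path(dir, paste0(name, "_mu.nii.gz")), vox)
  writeVolume(phantom@labels * 1.0, file.path(dir, paste0(name, "_labels.nii.gz")), vox)
  h <- phantom@heart
  meta <- list(seed = phantom@seed, voxelSize = vox,
               shape = as.integer(phantom@grid@shape),
               classMu = as.list(phantom@classMu),
               heart = list(center = h@center, axis = h@axis,
                            outerRadius = h@outerRadius,
                            innerRadius = h@innerRadius,
                            outerLength = h@outerLength,
                            innerLength = h@innerLength,
                            wallAngles = as.list(h@wallAngles)))
  side <- file.path(dir, paste0(name, ".yaml"))
  yaml::write_yaml(meta, side)
  invisible(side)
}

#' Write / read a tissue model as YAML
#'
#' @param model a [TissueModel-class]
#' @param path YAML path
#' @return `writeTissueModel`: the path, invisibly; `readTissueModel`: a
#'   [TissueModel-class].
#' @export
writeTissueModel <- function(model, path) {
  yaml::write_yaml(list(classMu = as.list(model@classMu),
                        provenance = model@provenance), path)
  invisible(path)
}

#' @rdname writeTissueModel
#' @export
readTissueModel <- function(path) {
  y <- yaml::read_yaml(path)
  new("TissueModel",
      classMu = structure(as.numeric(unlist(y$classMu)),
                          names = as.character(0:5)),
      provenance = y$provenance)
}
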