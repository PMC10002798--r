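#' Experiment configuration for the three-arm study
#'
#' Describes a desk-scale cohort experiment comparing attenuation
#' compensation with a scatter-window/segmentation-derived map (SLAC arm)
#' against CT-based compensation (CTAC) and no compensation (NAC) on the
#' defect-detection task. Training and test patients are disjoint by
#' construction (disjoint seed ranges), as are defect-present and
#' defect-absent test patients.
#'
#' @param nTrain training patients (tissue-model / network fitting)
#' @param nPresent defect-present test patients
#' @param nAbsent defect-absent test patients
#' @param walls wall restriction for the observer study (default
#'   "inferior", matching the evaluation design; `NULL` keeps all 27 defect
#'   types)
#' @param seed master seed; every stage derives its own stream from it
#' @param grid a [VolumeGrid-class]
#' @param nAngles projection views over 180 degrees
#' @param totalCounts total photopeak counts per study
#' @param photoSubsets,photoIters OSEM subsets/iterations for photopeak
#'   reconstructions
#' @param scatterSubsets,scatterIters OSEM settings for the scatter window
#' @param segBackend segmentation backend for the SLAC arm: deterministic
#'   classical segmenter (`"fallback"`), trained network (`"mceun"`), or
#'   ground-truth labels (`"truth"`)
#' @param scatterFraction scatter-to-primary fraction
#' @param ctNoiseSd pseudo-CT noise (HU) for the CTAC arm
#' @param nBoot bootstrap replicates for AUC confidence intervals
#' @param mrfIters ICM sweeps when segmenting training attenuation maps
#' @param mceunEpochs training epochs when `segBackend = "mceun"`
#' @param phantom anatomy parameter set from [phantomParams()]
#' @return List of class `"ExperimentConfig"`.
#' @export
experimentConfig <- function(nTrain = 10L, nPresent = 12L, nAbsent = 12L,
                             walls = "inferior", seed = 2026L,
                             grid = volumeGrid(), nAngles = 32L,
                             totalCounts = 4e6, photoSubsets = 8L,
                             photoIters = 2L, scatterSubsets = 4L,
                             scatterIters = 5L,
                             segBackend = c("fallback", "mceun", "truth"),
                             scatterFraction = 0.3, ctNoiseSd = 20,
                             nBoot = 500L, mrfIters = 6L,
                             mceunEpochs = 10L,
                             phantom = phantomParams()) {
  segBackend <- match.arg(segBackend)
  stopifnot(nTrain >= 1, nPresent >= 1, nAbsent >= 1)
  structure(list(nTrain = as.integer(nTrain), nPresent = as.integer(nPresent),
                 nAbsent = as.integer(nAbsent), walls = walls,
                 seed = as.integer(seed), grid = grid,
                 nAngles = as.integer(nAngles), totalCounts = totalCounts,
                 photoSubsets = as.integer(photoSubsets),
                 photoIters = as.integer(photoIters),
                 scatterSubsets = as.integer(scatterSubsets),
                 scatterIters = as.integer(scatterIters),
                 segBackend = segBackend, scatterFraction = scatterFraction,
                 ctNoiseSd = ctNoiseSd, nBoot = as.integer(nBoot),
                 mrfIters = as.integer(mrfIters),
                 mceunEpochs = as.integer(mceunEpochs), phantom = phantom),
            class = "ExperimentConfig")
}

#' Build the study design table
#'
#' Cross product of defect-present test patients with the in-scope defect
#' specifications, plus one row per (defect-absent patient, specification)
#' pair; absent records carry no inserted defect (images from the same
#' patient are identical) but keep the specification that defines the ROI
#' placement.
#'
#' @param config an [experimentConfig()] list
#' @param catalog defect catalog (default [defectCatalog()])
#' @return `data.frame` with one row per record and attribute `"counts"`.
#' @export
#' @examples
#' d <- buildStudyDesign(experimentConfig(nPresent = 71, nAbsent = 69,
#'                                        walls = NULL))
#' attr(d, "counts")
buildStudyDesign <- function(config, catalog = defectCatalog()) {
  if (!length(catalog)) stop("empty defect catalog")
  if (config$nPresent < 1 || config$nAbsent < 1)
    stop("zero patients in a group")
  keep <- if (is.null(config$walls)) seq_along(catalog) else
    which(vapply(catalog, function(s) s@wall %in% config$walls, logical(1)))
  if (!length(keep)) stop("wall restriction leaves no defect types")
  mk <- function(patients, group) {
    do.call(rbind, lapply(patients, function(p)
      data.frame(patient = p, group = group, specIdx = keep,
                 wall = vapply(catalog[keep], function(s) s@wall, ""),
                 extentDeg = vapply(catalog[keep], function(s) s@extentDeg, 0),
                 severity = vapply(catalog[keep], function(s) s@severity, 0))))
  }
  present <- mk(sprintf("present-%02d", seq_len(config$nPresent)), "present")
  absent <- mk(sprintf("absent-%02d", seq_len(config$nAbsent)), "absent")
  design <- rbind(present, absent)
  design$record <- seq_len(nrow(design))
  attr(design, "counts") <- c(present = nrow(present), absent = nrow(absent),
                              total = nrow(design), types = length(keep))
  design
}

# Per-patient preparation: phantom, noisy defect-free projections, and the
# three candidate attenuation maps.
preparePatient <- function(id, seed, config, geom, tissue, net = NULL) {
  ph <- generatePhantom(seed, params = config$phantom, grid = config$grid)
  vox <- config$grid@voxelSize
  proj <- projectPhantom(ph, geom, scatterFraction = config$scatterFraction)
  noisy <- addPoissonNoise(proj, config$totalCounts, seed = seed + 31L)
  init <- reconstructInitialEstimates(noisy,
    scatterConfig = reconConfig(config$scatterSubsets, config$scatterIters,
                                useAttenuation = FALSE),
    photoConfig = reconConfig(config$photoSubsets, config$photoIters,
                              useAttenuation = FALSE))
  segLabels <- switch(config$segBackend,
    fallback = classicalFallbackSegment(init$scatter, init$photopeak),
    truth = ph@labels,
    mceun = predictSegmentation(net, init$scatter, init$photopeak))
  muSLAC <- assignMu(segLabels, tissue)
  hu <- simulatePseudoCT(ph, noiseSd = config$ctNoiseSd, seed = seed + 47L)
  muCTAC <- bilinearHuToMu(hu)
  list(id = id, seed = as.integer(seed), phantom = ph, projections = noisy,
       muSLAC = muSLAC, muCTAC = muCTAC, heart = ph@heart,
       segLabels = segLabels)
}

#' Prepare a study: cohort simulation and attenuation-map estimation
#'
#' Generates training and test phantoms, fits the tissue model (MRF
#' segmentation of the training CT-derived attenuation maps, class-mean
#' pooling), simulates noisy two-window projection data for every test
#' patient, estimates the per-patient SLAC and CTAC attenuation maps, and
#' simulates the per-record defect-present photopeak data. The same noise
#' realization is shared by all three arms of a record.
#'
#' @param config an [experimentConfig()] list
#' @param verbose print stage progress?
#' @return List of class `"SlacStudy"`.
#' @export
prepareStudy <- function(config = experimentConfig(), verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  base <- config$seed
  geom <- acquisitionGeometry(nAngles = config$nAngles,
                              detectorBins = c(config$grid@shape[1],
                                               config$grid@shape[3]),
                              binSize = config$grid@voxelSize)
  say("stage 1/3: training cohort (n = ", config$nTrain, ")")
  muMaps <- list(); labMaps <- list(); trainPairs <- list()
  for (i in seq_len(config$nTrain)) {
    ph <- generatePhantom(base + 100L + i, params = config$phantom,
                          grid = config$grid)
    hu <- simulatePseudoCT(ph, noiseSd = config$ctNoiseSd,
                           seed = base + 100L + i)
    muCT <- bilinearHuToMu(hu)
    labMaps[[i]] <- mrfSegment(muCT, nIters = config$mrfIters)
    muMaps[[i]] <- muCT
    if (config$segBackend == "mceun") {
      proj <- projectPhantom(ph, geom,
                             scatterFraction = config$scatterFraction)
      noisy <- addPoissonNoise(proj, config$totalCounts,
                               seed = base + 150L + i)
      init <- reconstructInitialEstimates(noisy,
        scatterConfig = reconConfig(config$scatterSubsets,
                                    config$scatterIters,
                                    useAttenuation = FALSE),
        photoConfig = reconConfig(config$photoSubsets, config$photoIters,
                                  useAttenuation = FALSE))
      ks <- unique(round(seq(8, config$grid@shape[3] - 8, length.out = 8)))
      for (k in ks)
        trainPairs[[length(trainPairs) + 1L]] <- list(
          input = array(c(init$scatter[, , k], init$photopeak[, , k]),
                        c(config$grid@shape[1], config$grid@shape[2], 2)),
          labels = ph@labels[, , k])
    }
  }
  tissue <- fitTissueModel(muMaps, labMaps,
                           provenance = sprintf("train-seed-%d", base))
  net <- NULL
  if (config$segBackend == "mceun") {
    say("stage 1b: training McEUN on ", length(trainPairs), " slices")
    net <- buildMcEUN(mceunConfig(), seed = base + 9L)
    net <- trainMcEUN(net, trainPairs, epochs = config$mceunEpochs,
                      seed = base + 11L, cv = FALSE)$net
  }
  say("stage 2/3: test cohort (n = ", config$nPresent + config$nAbsent, ")")
  catalog <- defectCatalog()
  design <- buildStudyDesign(config, catalog)
  ids <- unique(design$patient)
  patients <- list()
  for (j in seq_along(ids)) {
    patients[[ids[j]]] <- preparePatient(ids[j], base + 200L + j, config,
                                         geom, tissue, net)
  }
  say("stage 3/3: defect-present record simulation")
  recProj <- vector("list", nrow(design))
  centroids <- vector("list", nrow(design))
  for (r in seq_len(nrow(design))) {
    pat <- patients[[design$patient[r]]]
    spec <- catalog[[design$specIdx[r]]]
    centroids[[r]] <- defectCentroid(pat$phantom, spec)
    if (design$group[r] == "present") {
      phd <- insertDefect(pat$phantom, spec)
      pk <- forwardProject(phd@activity, phd@mu, geom,
                           voxelSize = config$grid@voxelSize)
      ps <- projectionSet(geom, pk, scatter = pat$projections@scatter)
      recProj[[r]] <- addPoissonNoise(ps, config$totalCounts,
                                      seed = base + 400L + r)@photopeak
    }
  }
  for (id in names(patients)) {
    patients[[id]]$phantom <- NULL   # volumes no longer needed; keep heart
  }
  gc(FALSE)
  structure(list(config = config, geometry = geom, tissueModel = tissue,
                 net = net, design = design, patients = patients,
                 recordProjections = recProj, centroids = centroids,
                 catalog = catalog),
            class = "SlacStudy")
}

#' Run one arm of the experiment
#'
#' Reconstructs every record of the study with the arm's attenuation input
#' (SLAC: segmentation-derived map; CTAC: pseudo-CT bilinear map; NAC:
#' none — the NAC arm never reads an attenuation map), applies identical
#' post-processing (Butterworth filter, short-axis reorientation), and
#' extracts the 32x32 observer ROI centered on the record's defect
#' centroid. Defect-absent records reuse their patient's single defect-free
#' reconstruction.
#'
#' @param study a `"SlacStudy"` from [prepareStudy()]
#' @param arm one of "SLAC", "CTAC", "NAC"
#' @param verbose print progress?
#' @return List with `rois` (array `[32, 32, nRecords]`), `labels`
#'   (0/1 per record), `patientVolumes` (filtered short-axis defect-free
#'   volume per patient), and `arm`.
#' @export
runArm <- function(study, arm = c("SLAC", "CTAC", "NAC"), verbose = TRUE) {
  arm <- match.arg(arm)
  cfg <- study$config
  vox <- cfg$grid@voxelSize
  muOf <- function(pat) switch(arm, SLAC = pat$muSLAC, CTAC = pat$muCTAC,
                               NAC = NULL)
  if (arm != "NAC") {
    bad <- vapply(study$patients, function(p) is.null(muOf(p)), logical(1))
    if (any(bad)) stop("missing attenuation map for arm ", arm)
  }
  resamplers <- lapply(study$patients, function(p)
    makeShortAxisResampler(p$heart, cfg$grid@shape, vox))
  post <- function(vol, id) {
    v <- butterworthFilter(vol, order = 5, cutoffCm = 0.44, voxelSize = vox)
    resamplers[[id]](v)
  }
  n <- nrow(study$design)
  rois <- array(0, c(32, 32, n))
  labels <- integer(n)
  patientVolumes <- list()
  # one batched reconstruction per patient: the defect-free scan plus all
  # of the patient's defect-present records share the same system model
  for (id in names(study$patients)) {
    pat <- study$patients[[id]]
    mu <- muOf(pat)
    cfgR <- reconConfig(cfg$photoSubsets, cfg$photoIters,
                        useAttenuation = !is.null(mu), muMap = mu)
    recIdx <- which(study$design$patient == id &
                    study$design$group == "present")
    ys <- c(list(pat$projections@photopeak),
            study$recordProjections[recIdx])
    recons <- osemBatch(ys, cfgR, study$geometry)
    patientVolumes[[id]] <- post(recons[[1]], id)
    for (k in seq_along(recIdx)) {
      r <- recIdx[k]
      labels[r] <- 1L
      sax <- post(recons[[k + 1]], id)
      cv <- shortAxisCoords(study$centroids[[r]], pat$heart,
                            cfg$grid@shape, vox)
      rois[, , r] <- extractROI(sax, cv)
    }
  }
  for (r in which(study$design$group == "absent")) {
    pat <- study$patients[[study$design$patient[r]]]
    cv <- shortAxisCoords(study$centroids[[r]], pat$heart, cfg$grid@shape,
                          vox)
    rois[, , r] <- extractROI(patientVolumes[[pat$id]], cv)
  }
  if (verbose) message("arm ", arm, ": ", n, " records reconstructed")
  list(rois = rois, labels = labels, patientVolumes = patientVolumes,
       arm = arm)
}

observerStudy <- function(armResult, nBoot, seed) {
  bank <- makeChannelBank()
  stats <- choScores(armResult$rois, armResult$labels, bank)
  emp <- empiricalRocAuc(stats, armResult$labels, nBoot = nBoot, seed = seed)
  bn <- binormalFit(stats, armResult$labels)
  new("ObserverStudyResult", statistics = stats,
      labels = as.integer(armResult$labels), roc = emp$roc, auc = emp$auc,
      aucCI = emp$ci, binormal = bn, method = armResult$arm)
}

#' Run the full three-arm experiment
#'
#' End-to-end: cohort preparation, per-arm reconstruction with identical
#' projections and post-processing (differing only in the attenuation
#' input), channelized-Hotelling observer study per arm, and fidelity
#' metrics of the SLAC and NAC arms against the CTAC reference. The report
#' records every seed, so it is regenerable bit-identically from its
#' manifest.
#'
#' @param config an [experimentConfig()] list
#' @param verbose print stage progress?
#' @return List of class `"SlacReport"`: per-arm
#'   [ObserverStudyResult-class] objects, AUC table, fidelity table,
#'   and the manifest.
#' @export
runFullExperiment <- function(config = experimentConfig(), verbose = TRUE) {
  t0 <- Sys.time()
  study <- prepareStudy(config, verbose = verbose)
  arms <- lapply(c("SLAC", "CTAC", "NAC"), function(a)
    runArm(study, a, verbose = verbose))
  names(arms) <- c("SLAC", "CTAC", "NAC")
  obs <- lapply(arms, observerStudy, nBoot = config$nBoot,
                seed = config$seed + 900L)
  aucTable <- data.frame(
    arm = names(obs),
    auc = vapply(obs, slot, numeric(1), "auc"),
    ciLow = vapply(obs, function(o) o@aucCI[1], numeric(1)),
    ciHigh = vapply(obs, function(o) o@aucCI[2], numeric(1)),
    aucBinormal = vapply(obs, function(o) o@binormal$auc, numeric(1)))
  fid <- function(a) {
    per <- t(vapply(names(arms$CTAC$patientVolumes), function(id)
      fidelityMetrics(arms[[a]]$patientVolumes[[id]],
                      arms$CTAC$patientVolumes[[id]]), numeric(2)))
    ci <- function(x) mean(x) + c(-1.96, 1.96) * sd(x) / sqrt(length(x))
    data.frame(arm = a, rmse = mean(per[, "rmse"]),
               rmseLow = ci(per[, "rmse"])[1], rmseHigh = ci(per[, "rmse"])[2],
               ssim = mean(per[, "ssim"]),
               ssimLow = ci(per[, "ssim"])[1], ssimHigh = ci(per[, "ssim"])[2])
  }
  fidTable <- rbind(fid("SLAC"), fid("NAC"))
  report <- structure(list(observer = obs, auc = aucTable,
                           fidelity = fidTable,
                           manifest = list(config = config,
                                           nRecords = nrow(study$design),
                                           counts = attr(study$design,
                                                         "counts"),
                                           elapsedMin = as.numeric(
                                             difftime(Sys.time(), t0,
                                                      units = "mins"))),
                           design = study$design),
                      class = "SlacReport")
  if (verbose) {
    message("AUC by arm:")
    for (i in seq_len(nrow(aucTable)))
      message(sprintf("  %-4s %.3f [%.3f, %.3f]", aucTable$arm[i],
                      aucTable$auc[i], aucTable$ciLow[i], aucTable$ciHigh[i]))
  }
  report
}

#' @export
print.SlacReport <- function(x, ...) {
  cat("Three-arm attenuation-compensation experiment\n")
  cat(sprintf("records: %d (present %d / absent %d)\n",
              x$manifest$counts["total"], x$manifest$counts["present"],
              x$manifest$counts["absent"]))
  cat("\nDefect-detection AUC (empirical [95% CI], binormal):\n")
  for (i in seq_len(nrow(x$auc)))
    cat(sprintf("  %-4s %.3f [%.3f, %.3f]  %.3f\n", x$auc$arm[i],
                x$auc$auc[i], x$auc$ciLow[i], x$auc$ciHigh[i],
                x$auc$aucBinormal[i]))
  cat("\nFidelity vs CTAC reference (mean [95% CI]):\n")
  for (i in seq_len(nrow(x$fidelity)))
    cat(sprintf("  %-4s RMSE %.4f [%.4f, %.4f]  SSIM %.3f [%.3f, %.3f]\n",
                x$fidelity$arm[i], x$fidelity$rmse[i], x$fidelity$rmseLow[i],
                x$fidelity$rmseHigh[i], x$fidelity$ssim[i],
                x$fidelity$ssimLow[i], x$fidelity$ssimHigh[i]))
  invisible(x)
}
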