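#' Bilinear HU to attenuation-coefficient conversion
#'
#' Piecewise-linear map with breakpoint at 0 HU (water): for HU <= 0 the
#' soft branch runs linearly from (-1000 HU, 0) to (0, muWater); for HU > 0
#' the bone branch has slope `boneSlope`. Output is clipped below at 0, so
#' the map is monotone non-decreasing.
#'
#' @param hu numeric array/vector of Hounsfield values
#' @param model a [BilinearModel-class]
#' @return Attenuation values (cm^-1), same shape as `hu`.
#' @export
#' @examples
#' bilinearHuToMu(c(-1000, -500, 0, 1000), bilinearModel())
bilinearHuToMu <- function(hu, model = bilinearModel()) {
  mu <- ifelse(hu <= 0, model@muWater * (1 + hu / 1000),
               model@muWater + model@boneSlope * hu)
  mu[mu < 0] <- 0
  if (is.array(hu)) mu <- array(mu, dim(hu))
  mu
}

#' Inverse of the bilinear conversion
#'
#' Maps attenuation coefficients back to HU (used to synthesize pseudo-CT
#' volumes). Exact inverse of [bilinearHuToMu()] for mu in [0, 0.5].
#'
#' @param mu attenuation values (cm^-1)
#' @param model a [BilinearModel-class]
#' @return HU values, same shape.
#' @export
muToHu <- function(mu, model = bilinearModel()) {
  hu <- ifelse(mu <= model@muWater, 1000 * (mu / model@muWater - 1),
               (mu - model@muWater) / model@boneSlope)
  if (is.array(mu)) hu <- array(hu, dim(mu))
  hu
}

#' Markov random field tissue segmentation
#'
#' Six-class segmentation of an attenuation map by a Potts-model MRF solved
#' with iterated conditional modes (ICM). The energy is the squared
#' intensity misfit to the class mean plus `beta` times the number of
#' disagreeing 6-neighbors. Labels are initialized by k-means on the
#' intensities; ICM sweeps use a two-color (checkerboard) schedule, so the
#' energy is non-increasing; class means are re-estimated after each sweep.
#' The patient-table class is resolved by a spatial prior: among non-air
#' clusters it is the one lying lowest along the anterior-posterior axis.
#'
#' @param mu finite 3-D attenuation map
#' @param nClasses number of classes (6)
#' @param beta Potts smoothness weight (default 0.5); the intensity misfit
#'   is scaled as a Gaussian log-likelihood, `(I - m)^2 / (2 sigma^2)` with
#'   `sigma` the within-class noise level estimated at initialization, so
#'   `beta` is comparable across maps
#' @param nIters number of ICM sweeps (default 10)
#' @param initCenters initial class-mean intensities for the k-means
#'   initialization (default: the nominal tissue coefficients)
#' @return Integer label array (values 0..5, the [tissueClasses()] coding),
#'   with attributes `"energy"` (per-sweep energy trace) and
#'   `"classMeans"` (intensity mean per output label).
#' @export
mrfSegment <- function(mu, nClasses = 6L, beta = 0.5, nIters = 10L,
                       initCenters = nominalClassMu()) {
  if (!all(is.finite(mu))) stop("mu must be finite")
  d <- dim(mu)
  vals <- as.vector(mu)
  if (length(unique(vals)) < nClasses)
    stop("fewer distinct intensities than classes")
  rng <- range(vals)
  # beta is specified on a normalized intensity scale so it is comparable
  # across maps; work in normalized units internally
  v <- (vals - rng[1]) / diff(rng)
  # initialize cluster centers at the nominal tissue coefficients (mapped to
  # the normalized scale); with equal-size random starts k-means tends to
  # split the dominant air class and merge small high-mu classes instead
  init <- sort(unique(pmin(pmax((initCenters - rng[1]) / diff(rng), 0), 1)))
  if (length(init) < nClasses)
    init <- seq(0, 1, length.out = nClasses)
  km <- tryCatch(kmeans(v, centers = matrix(init), iter.max = 100),
                 error = function(e) NULL)
  if (is.null(km))   # fall back to random data-point starts
    for (attempt in 1:5) {
      km <- withSeed(1299L + attempt,
                     tryCatch(kmeans(v, centers = nClasses, nstart = 5,
                                     iter.max = 100),
                              error = function(e) NULL))
      if (!is.null(km)) break
    }
  if (is.null(km)) stop("k-means initialization failed")
  lab <- array(km$cluster, d)               # clusters 1..K
  means <- as.vector(km$centers)
  # Gaussian-likelihood scaling of the misfit: within-class noise level from
  # the initialization (floored so a noiseless map reduces to pure
  # nearest-mean classification)
  sigma <- max(sqrt(mean((v - means[km$cluster])^2)), 1e-4)

  nbrCount <- function(labArr, cl) {
    ind <- labArr == cl
    shift3d(ind, 1, 0, 0) + shift3d(ind, -1, 0, 0) +
      shift3d(ind, 0, 1, 0) + shift3d(ind, 0, -1, 0) +
      shift3d(ind, 0, 0, 1) + shift3d(ind, 0, 0, -1)
  }
  nNbr <- {
    one <- array(TRUE, d)
    nbrTot <- shift3d(one, 1, 0, 0) + shift3d(one, -1, 0, 0) +
      shift3d(one, 0, 1, 0) + shift3d(one, 0, -1, 0) +
      shift3d(one, 0, 0, 1) + shift3d(one, 0, 0, -1)
    nbrTot
  }
  vArr <- array(v, d)
  parity <- (outer(outer(seq_len(d[1]), seq_len(d[2]), `+`) %% 2,
                   seq_len(d[3]), `+`)) %% 2

  energyOf <- function(labArr, m) {
    mis <- sum((vArr - array(m[labArr], d))^2) / (2 * sigma^2)
    dis <- 0
    for (cl in seq_len(nClasses)) {
      ind <- labArr == cl
      dis <- dis + sum(ind * (nNbr - nbrCount(labArr, cl)))
    }
    mis + beta * dis / 2
  }

  energy <- numeric(nIters)
  for (it in seq_len(nIters)) {
    for (col in 0:1) {
      cost <- array(Inf, c(d, nClasses))
      for (cl in seq_len(nClasses))
        cost[, , , cl] <- (vArr - means[cl])^2 / (2 * sigma^2) +
          beta * (nNbr - nbrCount(lab, cl))
      best <- array(1L, d)
      bestCost <- cost[, , , 1]
      for (cl in 2:nClasses) {
        better <- cost[, , , cl] < bestCost
        best[better] <- cl
        bestCost[better] <- cost[, , , cl][better]
      }
      upd <- parity == col
      lab[upd] <- best[upd]
    }
    for (cl in seq_len(nClasses)) {
      sel <- lab == cl
      if (any(sel)) means[cl] <- mean(vArr[sel])
    }
    energy[it] <- energyOf(lab, means)
  }

  # semantic relabeling: lowest-mean cluster is background; among the rest
  # the table is the cluster lying lowest in y; remaining four ascend in
  # intensity as lungs < skin/adipose < soft tissue < bones
  muMeans <- vapply(seq_len(nClasses), function(cl) {
    sel <- lab == cl
    if (any(sel)) mean(mu[sel]) else Inf
  }, numeric(1))
  present <- which(is.finite(muMeans))
  bg <- present[which.min(muMeans[present])]
  rest <- setdiff(present, bg)
  medY <- vapply(rest, function(cl) {
    idx <- which(lab == cl, arr.ind = TRUE)
    stats::median(idx[, 2])
  }, numeric(1))
  tbl <- rest[which.min(medY)]
  rest2 <- setdiff(rest, tbl)
  ord <- rest2[order(muMeans[rest2])]
  mapTo <- integer(nClasses)
  mapTo[bg] <- 0L
  mapTo[tbl] <- 5L
  targets <- c(3L, 1L, 2L, 4L)  # lungs, skin/adipose, soft, bones
  mapTo[ord] <- targets[seq_along(ord)]
  out <- array(mapTo[lab], d)
  outMeans <- vapply(0:5, function(cl) {
    sel <- out == cl
    if (any(sel)) mean(mu[sel]) else NA_real_
  }, numeric(1))
  attr(out, "energy") <- energy
  attr(out, "classMeans") <- structure(outMeans, names = as.character(0:5))
  out
}

#' Fit the tissue model: per-class mean attenuation coefficients
#'
#' Pools all voxels of each class over the training pairs and averages,
#' yielding the predefined attenuation coefficients assigned to segmented
#' regions at inference time.
#'
#' @param muMaps list of training attenuation maps (or a single array)
#' @param labelMaps list of matching label maps (values 0..5)
#' @param provenance free-text training-set identifier
#' @return A [TissueModel-class].
#' @export
fitTissueModel <- function(muMaps, labelMaps, provenance = "training") {
  if (is.array(muMaps)) muMaps <- list(muMaps)
  if (is.array(labelMaps)) labelMaps <- list(labelMaps)
  stopifnot(length(muMaps) >= 1, length(muMaps) == length(labelMaps))
  sums <- numeric(6); counts <- numeric(6)
  for (i in seq_along(muMaps)) {
    for (cl in 0:5) {
      sel <- labelMaps[[i]] == cl
      sums[cl + 1] <- sums[cl + 1] + sum(muMaps[[i]][sel])
      counts[cl + 1] <- counts[cl + 1] + sum(sel)
    }
  }
  if (any(counts == 0)) {
    missing <- names(tissueClasses())[counts == 0]
    stop("no training voxels for class: ", paste(missing, collapse = ", "))
  }
  cm <- sums / counts
  cm[1] <- 0  # background is air by definition
  new("TissueModel", classMu = structure(pmin(pmax(cm, 0), 0.5),
                                         names = as.character(0:5)),
      provenance = provenance)
}

#' Assign predefined attenuation coefficients to a segmentation
#'
#' Piecewise-constant attenuation map from a label map and a fitted
#' [TissueModel-class]; the output takes at most six distinct values.
#'
#' @param labels integer array with values 0..5
#' @param model a [TissueModel-class]
#' @return Attenuation map (cm^-1), same shape as `labels`.
#' @export
assignMu <- function(labels, model) {
  stopifnot(is(model, "TissueModel"))
  u <- unique(as.vector(labels))
  if (!all(u %in% 0:5))
    stop("unknown label(s): ", paste(setdiff(u, 0:5), collapse = ", "))
  array(model@classMu[as.character(as.vector(labels))], dim(labels))
}
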