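#' Nominal per-class attenuation coefficients at 140 keV
#'
#' Background 0, lungs 0.04, skin/adipose 0.14, muscles/organs 0.154,
#' bones 0.25, patient table 0.20 cm^-1. Each generated phantom multiplies
#' these by a small per-class jitter so that class-mean estimation from
#' training data is a nontrivial task.
#'
#' @return Named numeric(6), names "0".."5".
#' @export
nominalClassMu <- function() {
  structure(c(0, 0.14, 0.154, 0.04, 0.25, 0.20), names = as.character(0:5))
}

#' The catalog of 27 parametric perfusion defects
#'
#' Full cross product of three circumferential extents (30, 60, 90 degrees),
#' three severities (10%, 25%, 50% activity reduction) and three LV walls
#' (anterior, inferior, lateral), ordered by wall, then extent, then severity,
#' all ascending.
#'
#' @return List of 27 [DefectSpec-class] objects.
#' @export
#' @examples
#' length(defectCatalog())
defectCatalog <- function() {
  specs <- list()
  for (wall in c("anterior", "inferior", "lateral"))
    for (ext in c(30, 60, 90))
      for (sev in c(0.10, 0.25, 0.50))
        specs[[length(specs) + 1L]] <- defectSpec(ext, sev, wall)
  specs
}

#' Anatomy parameter set for phantom generation
#'
#' All lengths in cm, in world coordinates with the origin at the grid
#' center, +x patient left, +y anterior, +z towards the head. Each parameter
#' has a documented admissible range; `generatePhantom()` rejects values
#' outside it.
#'
#' @param bodyA,bodyB transverse body semi-axes (range 8-20 / 6-16)
#' @param skinThickness skin/adipose rind thickness (0.5-3)
#' @param lungScale global lung size factor (0.6-1.3)
#' @param heartCenter numeric(3) LV base center (each within +/- 12)
#' @param heartScale LV size factor (0.7-1.3)
#' @param myoUptake myocardium-to-soft-tissue uptake ratio (3-12)
#' @param liverUptake liver-to-soft-tissue uptake ratio (1-4)
#' @param diaphragmJitter half-range (cm) of the per-patient diaphragm
#'   level: lungs and liver shift together along the scanner axis by
#'   `U(-diaphragmJitter, diaphragmJitter)` (0-4; default 2.5). This is the
#'   main patient-to-patient source of locally varying attenuation over the
#'   inferior wall, the anatomy behind the classic diaphragmatic artifact
#'   of uncompensated imaging.
#' @param muJitter per-class multiplicative attenuation jitter amplitude
#'   (0-0.2; the generator draws per class from
#'   `U(1 - muJitter, 1 + muJitter)`)
#' @param jitter anatomical jitter amplitude for sizes/positions (0-0.2)
#' @return Named list of parameters.
#' @export
phantomParams <- function(bodyA = 15, bodyB = 10.5, skinThickness = 1.1,
                          lungScale = 1, heartCenter = c(4.8, 2.6, 5.5),
                          heartScale = 1, myoUptake = 6, liverUptake = 2.2,
                          diaphragmJitter = 2.5, muJitter = 0.05,
                          jitter = 0.12) {
  list(bodyA = bodyA, bodyB = bodyB, skinThickness = skinThickness,
       lungScale = lungScale, heartCenter = heartCenter,
       heartScale = heartScale, myoUptake = myoUptake,
       liverUptake = liverUptake, diaphragmJitter = diaphragmJitter,
       muJitter = muJitter, jitter = jitter)
}

checkPhantomParams <- function(p) {
  chk <- function(ok, what)
    if (!all(ok)) stop("phantom parameter out of range: ", what, call. = FALSE)
  chk(p$bodyA >= 8 && p$bodyA <= 20, "bodyA")
  chk(p$bodyB >= 6 && p$bodyB <= 16, "bodyB")
  chk(p$skinThickness >= 0.5 && p$skinThickness <= 3, "skinThickness")
  chk(p$lungScale >= 0.6 && p$lungScale <= 1.3, "lungScale")
  chk(all(abs(p$heartCenter) <= 12), "heartCenter")
  chk(p$heartScale >= 0.7 && p$heartScale <= 1.3, "heartScale")
  chk(p$myoUptake >= 3 && p$myoUptake <= 12, "myoUptake")
  chk(p$liverUptake >= 1 && p$liverUptake <= 4, "liverUptake")
  chk(p$diaphragmJitter >= 0 && p$diaphragmJitter <= 4, "diaphragmJitter")
  chk(p$muJitter >= 0 && p$muJitter <= 0.2, "muJitter")
  chk(p$jitter >= 0 && p$jitter <= 0.2, "jitter")
  invisible(p)
}

# Orthonormal short-axis frame (u, v, w) of a heart: w is the long axis,
# u the in-plane reference at 0 degrees (lateral), v = u x w so that the
# anterior wall sits at +90 degrees.
heartFrame <- function(heart) {
  w <- heart@axis
  u <- c(1, 0, 0) - sum(c(1, 0, 0) * w) * w
  if (sqrt(sum(u^2)) < 1e-6) u <- c(0, 1, 0) - sum(c(0, 1, 0) * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(u[2] * w[3] - u[3] * w[2],
         u[3] * w[1] - u[1] * w[3],
         u[1] * w[2] - u[2] * w[1])
  list(u = u, v = v, w = w)
}

# Logical mask of the myocardial shell (and optionally cavity) plus the
# cylindrical coordinates of every voxel in the heart frame.
heartMasks <- function(heart, X, Y, Z) {
  f <- heartFrame(heart)
  qx <- X - heart@center[1]; qy <- Y - heart@center[2]; qz <- Z - heart@center[3]
  t <- qx * f$w[1] + qy * f$w[2] + qz * f$w[3]
  pu <- qx * f$u[1] + qy * f$u[2] + qz * f$u[3]
  pv <- qx * f$v[1] + qy * f$v[2] + qz * f$v[3]
  rho2 <- pu^2 + pv^2
  inOuter <- t >= 0 & (rho2 / heart@outerRadius^2 +
                       t^2 / heart@outerLength^2) <= 1
  inInner <- t >= 0 & (rho2 / heart@innerRadius^2 +
                       t^2 / heart@innerLength^2) < 1
  phi <- (atan2(pv, pu) * 180 / pi) %% 360
  list(shell = inOuter & !inInner, cavity = inInner, phi = phi, t = t)
}

#' Generate a randomized digital thorax phantom
#'
#' Builds a body with skin/adipose rind, two lungs, spine and sternum,
#' liver, an LV myocardial shell with blood-pool cavity, and a flat patient
#' table, on the requested grid. Anatomy (sizes, positions, uptake ratios)
#' and per-class attenuation coefficients are jittered per seed, so the
#' phantom is a pure function of `(seed, params, grid)`.
#'
#' @param seed nonnegative integer seed
#' @param params parameter list from [phantomParams()]
#' @param grid a [VolumeGrid-class]
#' @return A [PhantomInstance-class].
#' @export
#' @examples
#' ph <- generatePhantom(1, grid = volumeGrid(c(32, 32, 32), 1.36))
#' table(ph@labels)
generatePhantom <- function(seed, params = phantomParams(),
                            grid = volumeGrid()) {
  if (seed < 0) stop("seed must be >= 0")
  checkPhantomParams(params)
  p <- params
  withSeed(seed + 20902L, {
    j <- function(lo, hi) runif(1, lo, hi)
    ja <- 1 + p$jitter
    bodyA <- p$bodyA * j(2 - ja, ja)
    bodyB <- p$bodyB * j(2 - ja, ja)
    lungS <- p$lungScale * j(2 - ja, ja)
    heartC <- p$heartCenter + runif(3, -0.8, 0.8) * (p$jitter / 0.08)
    heartS <- p$heartScale * j(1 - p$jitter / 2, 1 + p$jitter / 2)
    myoUp <- p$myoUptake * j(2 - ja, ja)
    livUp <- p$liverUptake * j(0.6, 1.4)   # sub-diaphragmatic uptake varies
                                           # strongly across stress studies
    classMu <- nominalClassMu() *
      c(1, runif(5, 1 - p$muJitter, 1 + p$muJitter))
    axis0 <- c(0.5, 0.25, -0.83) + rnorm(3, 0, 0.03 * (p$jitter / 0.08))
    dzDia <- runif(1, -p$diaphragmJitter, p$diaphragmJitter)

    d <- grid@shape; vox <- grid@voxelSize
    x <- axisCoords(d[1], vox); y <- axisCoords(d[2], vox)
    z <- axisCoords(d[3], vox)
    X <- array(rep(x, times = d[2] * d[3]), d)
    Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
    Z <- array(rep(z, each = d[1] * d[2]), d)

    sc <- min(1, vox * min(d) / 43.5)  # shrink organs on small test grids
    bodyA <- bodyA * sc; bodyB <- bodyB * sc

    rb2 <- (X / bodyA)^2 + (Y / bodyB)^2
    body <- rb2 <= 1
    t <- p$skinThickness * sc
    inner <- (X / (bodyA - t))^2 + (Y / (bodyB - t))^2 <= 1
    skin <- body & !inner

    heart <- heartGeometry(center = heartC * sc, axis = axis0,
                           outerRadius = 3.5 * heartS * sc,
                           innerRadius = 2.0 * heartS * sc,
                           outerLength = 7.5 * heartS * sc,
                           innerLength = 6.0 * heartS * sc)
    hm <- heartMasks(heart, X, Y, Z)
    heartRegion <- hm$shell | hm$cavity

    ell <- function(c0, s) ((X - c0[1]) / s[1])^2 + ((Y - c0[2]) / s[2])^2 +
                           ((Z - c0[3]) / s[3])^2 <= 1
    lungR <- ell(c(-5.8, 1.3, 2.5 + dzDia) * sc,
                 c(4.3, 6.0, 11.5) * lungS * sc)
    lungL <- ell(c(6.1, 0.8, 3.0 + dzDia) * sc,
                 c(3.6, 5.2, 10.5) * lungS * sc)
    lungs <- (lungR | lungL) & inner & !heartRegion

    spine <- ((X / (1.7 * sc))^2 + ((Y + 7.3 * sc) / (1.7 * sc))^2) <= 1
    sternum <- abs(X) <= 1.5 * sc & abs(Y - (bodyB - t - 0.9 * sc)) <= 0.7 * sc &
               abs(Z - 2 * sc) <= 10 * sc
    bones <- (spine | sternum) & inner & !lungs & !heartRegion

    liver <- ell(c(-5.2, -1.8, -11 + dzDia) * sc, c(7, 5.5, 6.5) * sc) & inner &
             !lungs & !bones & !heartRegion

    tableGap <- 1.2 * sc; tableTh <- 1.4 * sc
    tbl <- Y <= -(bodyB + tableGap) & Y >= -(bodyB + tableGap + tableTh) &
           abs(X) <= 13 * sc & !body

    shell <- hm$shell & inner
    cavity <- hm$cavity & inner

    labels <- array(0L, d)
    labels[body] <- 2L
    labels[skin] <- 1L
    labels[lungs] <- 3L
    labels[bones] <- 4L
    labels[tbl] <- 5L
    # guarantee all six classes on very small grids
    for (cl in 0:5) if (!any(labels == cl))
      stop("degenerate phantom: class ", cl, " empty; enlarge the grid")

    activity <- array(0, d)
    activity[labels == 2L] <- 1
    activity[labels == 1L] <- 0.3
    activity[labels == 3L] <- 0.2
    activity[labels == 4L] <- 0.4
    activity[liver & labels == 2L] <- livUp
    activity[cavity & labels == 2L] <- 0.8
    activity[shell & labels == 2L] <- myoUp

    mu <- array(classMu[["0"]], d)
    for (cl in 1:5) mu[labels == cl] <- classMu[[as.character(cl)]]

    new("PhantomInstance", grid = grid, activity = activity, mu = mu,
        labels = labels, heart = heart, classMu = classMu,
        seed = as.integer(seed), params = params)
  })
}

# In-sector myocardial mask for a defect spec (sharp sector edges; the
# defect spans the full apex-to-base extent of the shell).
defectMask <- function(phantom, spec) {
  d <- phantom@grid@shape; vox <- phantom@grid@voxelSize
  x <- axisCoords(d[1], vox); y <- axisCoords(d[2], vox); z <- axisCoords(d[3], vox)
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)
  hm <- heartMasks(phantom@heart, X, Y, Z)
  ref <- phantom@heart@wallAngles[[spec@wall]]
  dphi <- abs(((hm$phi - ref + 180) %% 360) - 180)
  hm$shell & dphi <= spec@extentDeg / 2
}

#' Insert a perfusion defect into a phantom
#'
#' Multiplies the activity of myocardial-shell voxels whose circumferential
#' angle lies within `extentDeg` centered on the wall's reference angle by
#' `1 - severity`. Attenuation map and labels are unchanged.
#'
#' @param phantom a [PhantomInstance-class]
#' @param spec a [DefectSpec-class]
#' @return A new [PhantomInstance-class] with reduced in-sector activity.
#' @export
insertDefect <- function(phantom, spec) {
  stopifnot(is(phantom, "PhantomInstance"), is(spec, "DefectSpec"))
  m <- defectMask(phantom, spec)
  if (!any(m)) stop("defect sector does not intersect the myocardium")
  phantom@activity[m] <- phantom@activity[m] * (1 - spec@severity)
  phantom
}

#' World-coordinate centroid of a defect
#'
#' Mean position (cm) of the in-sector myocardial voxels; used to center the
#' observer ROI. Known exactly by construction for synthetic phantoms.
#'
#' @param phantom a [PhantomInstance-class]
#' @param spec a [DefectSpec-class]
#' @return numeric(3) world coordinates.
#' @export
defectCentroid <- function(phantom, spec) {
  m <- defectMask(phantom, spec)
  if (!any(m)) stop("defect sector does not intersect the myocardium")
  d <- phantom@grid@shape; vox <- phantom@grid@voxelSize
  idx <- which(m, arr.ind = TRUE)
  c(mean(axisCoords(d[1], vox)[idx[, 1]]),
    mean(axisCoords(d[2], vox)[idx[, 2]]),
    mean(axisCoords(d[3], vox)[idx[, 3]]))
}

#' Simulate a pseudo-CT volume from a phantom
#'
#' Each voxel's Hounsfield value is the inverse-bilinear image of its
#' attenuation coefficient (so air maps to -1000 HU and a water-equivalent
#' voxel to 0 HU), plus optional zero-mean Gaussian noise. This supplies the
#' CT input that the bilinear HU-to-mu conversion consumes.
#'
#' @param phantom a [PhantomInstance-class]
#' @param noiseSd Gaussian noise standard deviation in HU
#' @param model a [BilinearModel-class]
#' @param seed seed for the noise draw
#' @return numeric 3-D array of HU values.
#' @export
simulatePseudoCT <- function(phantom, noiseSd = 0, model = bilinearModel(),
                             seed = phantom@seed) {
  hu <- muToHu(phantom@mu, model)
  if (noiseSd > 0)
    hu <- hu + withSeed(seed + 7L, array(rnorm(length(hu), 0, noiseSd),
                                         dim(hu)))
  hu
}
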