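test_that("all-zero projections are a fixed point of OSEM", {
  g <- geom32(8)
  rec <- osem(array(0, c(32, 32, 8)),
              reconConfig(4, 3, useAttenuation = FALSE), geometry = g)
  expect_true(all(rec == 0))
})

test_that("MLEM log-likelihood is non-decreasing on noiseless data", {
  ph <- phantom32()
  g <- geom32(16)
  proj <- forwardProject(ph@activity, ph@mu, g, voxelSize = 1.36)
  rec <- osem(proj, reconConfig(1, 50, useAttenuation = TRUE,
                                muMap = ph@mu),
              geometry = g, trackLoglik = TRUE)
  ll <- attr(rec, "loglik")
  expect_length(ll, 50L)
  expect_true(all(diff(ll) >= -1e-6 * abs(ll[-1])))
  expect_true(all(rec >= 0))
})

test_that("OSEM output is nonnegative for noisy data", {
  fx <- initEstimates64()
  rec <- osem(fx$noisy, reconConfig(8, 2, useAttenuation = FALSE),
              window = "photopeak")
  expect_true(all(rec >= 0))
  expect_identical(dim(rec), c(64L, 64L, 64L))
})

test_that("matched-model MLEM recovers a uniform disk within 5%", {
  d <- c(32, 32, 32)
  g <- acquisitionGeometry(nAngles = 32, detectorBins = c(32, 32),
                           binSize = 0.68)
  co <- coordArrays(d, 0.68)
  disk <- (co$X^2 + co$Y^2) <= 6^2
  act <- array(0, d); act[disk] <- 1
  proj <- forwardProject(act, NULL, g, useCdr = FALSE)
  rec <- osem(proj, reconConfig(1, 100, useAttenuation = FALSE,
                                useCdr = FALSE), geometry = g)
  interior <- (co$X^2 + co$Y^2) <= (6 - 2 * 0.68)^2
  expect_lt(max(abs(rec[interior] - 1)), 0.05)
})

test_that("subset count must divide the view count", {
  g <- geom32(9)
  expect_error(osem(array(1, c(32, 32, 9)),
                    reconConfig(4, 1, useAttenuation = FALSE), geometry = g),
               "divide")
})

test_that("initial estimates come back on the full grid, unit-normalized", {
  fx <- initEstimates64()
  expect_identical(dim(fx$init$scatter), c(64L, 64L, 64L))
  expect_identical(dim(fx$init$photopeak), c(64L, 64L, 64L))
  expect_equal(mean(fx$init$scatter[fx$init$scatter > 0]), 1,
               tolerance = 1e-8)
  expect_equal(mean(fx$init$photopeak[fx$init$photopeak > 0]), 1,
               tolerance = 1e-8)
})

test_that("zero scatter counts reconstruct to zero", {
  ph <- phantom32()
  g <- geom32(8)
  pk <- forwardProject(ph@activity, ph@mu, g, voxelSize = 1.36)
  ps <- projectionSet(g, pk, scatter = array(0, dim(pk)))
  init <- reconstructInitialEstimates(ps,
    scatterConfig = reconConfig(4, 2, useAttenuation = FALSE),
    photoConfig = reconConfig(4, 2, useAttenuation = FALSE))
  expect_true(all(init$scatter == 0))
})

test_that("Butterworth filter matches its closed form", {
  expect_equal(butterworthGain(0), 1)
  expect_equal(butterworthGain(0.44), 1 / sqrt(2), tolerance = 1e-9)
  nu <- seq(0.01, 0.7, by = 0.01)
  expect_true(all(diff(butterworthGain(nu)) < 0))
  # constant volume unchanged (DC gain exactly 1)
  const <- array(3.7, c(16, 16, 16))
  expect_equal(butterworthFilter(const, voxelSize = 0.68), const,
               tolerance = 1e-12)
  expect_warning(butterworthFilter(const, cutoffCm = 2, voxelSize = 0.68),
                 "Nyquist")
  # filtering suppresses a pure high-frequency mode by the predicted gain
  d <- c(16, 16, 16)
  k <- 4
  mode <- array(cos(2 * pi * k * (0:15) / 16), d)
  out <- butterworthFilter(mode, voxelSize = 0.68)
  nuK <- k / 16 / 0.68
  expect_equal(max(abs(out)), butterworthGain(nuK), tolerance = 1e-6)
})

test_that("short-axis reorientation is the identity for an aligned axis", {
  ph <- phantom32()
  vol <- ph@activity
  heart <- heartGeometry(center = c(1.3, -0.7, 2.1), axis = c(0, 0, 1),
                         outerRadius = 3, innerRadius = 2)
  sax <- reorientShortAxis(vol, heart, voxelSize = 1.36)
  expect_lt(max(abs(sax - vol)), 1e-6)
})

test_that("reorientation round trip restores the volume within 2%", {
  ph <- phantom64()
  vol <- slacspect:::gaussSmooth3d(ph@activity, 2)   # band-limit first
  heart <- ph@heart
  sax <- reorientShortAxis(vol, heart, voxelSize = 0.68)
  # inverse resample with the transposed rotation (direct oracle)
  M <- slacspect:::shortAxisRotation(heart)
  d <- dim(vol)
  co <- coordArrays(d, 0.68)
  P <- cbind(as.vector(co$X), as.vector(co$Y), as.vector(co$Z))
  src <- sweep(sweep(P, 2, heart@center) %*% M, 2, heart@center, `+`)
  vx <- sweep(src, 2, c(co$X[1], co$Y[1], co$Z[1])) / 0.68 + 1
  inv <- function(v) array(slacspect:::trilinearSample(v, vx), d)
  # compare only where the forward/inverse path stays inside the volume
  mask <- inv(reorientShortAxis(array(1, d), heart,
                                voxelSize = 0.68)) > 0.9999
  back <- inv(sax)
  relRmse <- sqrt(mean((back[mask] - vol[mask])^2)) /
    sqrt(mean(vol[mask]^2))
  expect_lt(relRmse, 0.02)
})

test_that("world points map to the short-axis position the rotation predicts", {
  ph <- phantom32()
  heart <- ph@heart
  pt <- heart@center + 2 * heart@axis
  cv <- shortAxisCoords(pt, heart, ph@grid@shape, 1.36)
  # oracle: the long axis becomes the output z axis through the center
  cc <- (heart@center / 1.36) + (ph@grid@shape - 1) / 2 + 1
  expect_equal(cv[1:2], cc[1:2], tolerance = 1e-8)
  expect_equal(cv[3], cc[3] + 2 / 1.36, tolerance = 1e-8)
  # a marker voxel lands where shortAxisCoords predicts
  vol <- array(0, ph@grid@shape)
  vol[20, 14, 18] <- 1
  w <- c((20 - 1 - 15.5), (14 - 1 - 15.5), (18 - 1 - 15.5)) * 1.36
  cvm <- shortAxisCoords(w, heart, ph@grid@shape, 1.36)
  sax <- reorientShortAxis(vol, heart, voxelSize = 1.36)
  peak <- arrayInd(which.max(sax), dim(sax))
  expect_lt(max(abs(as.vector(peak) - cvm)), 1)
})

test_that("ROI extraction crops 32x32 with the centroid at pixel (16,16)", {
  set.seed(3)
  vol <- array(rnorm(64^3), c(64, 64, 64))
  roi <- extractROI(vol, c(30, 25, 40))
  expect_identical(dim(roi), c(32L, 32L))
  expect_equal(roi[17, 17], vol[30, 25, 40])    # 0-based (16,16)
  # translation property: shifting the centroid shifts content oppositely
  roi2 <- extractROI(vol, c(32, 28, 40))
  expect_equal(roi2[1:28, 1:27], roi[3:30, 4:30])
  expect_warning(r3 <- extractROI(vol, c(5, 5, 1)), "zero-padded")
  expect_identical(dim(r3), c(32L, 32L))
  expect_error(extractROI(vol, c(30, 25, 99)), "outside")
})
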