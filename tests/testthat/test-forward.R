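test_that("forward and back projection are exact adjoints", {
  set.seed(1)
  g <- acquisitionGeometry(nAngles = 12, detectorBins = c(16, 16),
                           binSize = 0.68)
  mu <- array(runif(16^3, 0, 0.2), c(16, 16, 16))
  x <- array(runif(16^3), c(16, 16, 16))
  y <- array(runif(16 * 16 * 12), c(16, 16, 12))
  lhs <- sum(forwardProject(x, mu, g) * y)
  rhs <- sum(x * backProject(y, mu, g))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-5)
  # and without attenuation / CDR
  lhs2 <- sum(forwardProject(x, NULL, g, useCdr = FALSE) * y)
  rhs2 <- sum(x * backProject(y, NULL, g, useCdr = FALSE))
  expect_lt(abs(lhs2 - rhs2) / abs(lhs2), 1e-5)
})

test_that("projector linearity: zero activity gives zero projections", {
  g <- geom32(8)
  z <- forwardProject(array(0, c(32, 32, 32)), phantom32()@mu, g)
  expect_true(all(z == 0))
  expect_true(all(backProject(array(0, c(32, 32, 8)), NULL, g) == 0))
})

test_that("with mu = 0 and CDR off the projector equals plain ray sums", {
  set.seed(2)
  x8 <- array(runif(8^3), c(8, 8, 8))
  g <- acquisitionGeometry(nAngles = 4, angularRange = 360,
                           detectorBins = c(8, 8), binSize = 1)
  p <- forwardProject(x8, NULL, g, useCdr = FALSE, voxelSize = 1)
  # independent line-integral oracle at the four axis-aligned angles
  oracle <- list(
    apply(x8, c(1, 3), sum),                      # 0   deg: along +y
    apply(x8, c(2, 3), sum)[8:1, ],               # 90  deg
    apply(x8, c(1, 3), sum)[8:1, ],               # 180 deg
    apply(x8, c(2, 3), sum))                      # 270 deg
  for (a in 1:4)
    expect_lt(max(abs(p[, , a] - oracle[[a]])) / max(oracle[[a]]), 1e-6)
})

test_that("a point source behind a uniform slab obeys Beer-Lambert", {
  d <- c(32, 32, 32)
  act <- array(0, d); act[16, 10, 16] <- 1
  mu <- array(0, d); mu[, 14:20, ] <- 0.15       # 7 voxels of attenuator
  g <- acquisitionGeometry(nAngles = 4, detectorBins = c(32, 32),
                           binSize = 0.68, cdrSigma0 = 0, cdrSlope = 0)
  p0 <- forwardProject(act, array(0, d), g, useCdr = FALSE)
  p1 <- forwardProject(act, mu, g, useCdr = FALSE)
  ratio <- sum(p1[, , 1]) / sum(p0[, , 1])       # view along +y
  expect_equal(ratio, exp(-0.15 * 7 * 0.68), tolerance = 1e-6)
})

test_that("uniformly increasing attenuation never increases a projection bin", {
  ph <- phantom32()
  g <- geom32(8)
  p1 <- forwardProject(ph@activity, ph@mu, g)
  p2 <- forwardProject(ph@activity, ph@mu + 0.02, g)
  expect_true(all(p2 <= p1 + 1e-12))
})

test_that("backprojection preserves the symmetry of symmetric data", {
  g <- acquisitionGeometry(nAngles = 4, angularRange = 360,
                           detectorBins = c(16, 16), binSize = 1,
                           cdrSigma0 = 0, cdrSlope = 0)
  # identical circularly symmetric view at 0/90/180/270 degrees
  r <- outer((1:16) - 8.5, rep(1, 16))
  view <- exp(-(r^2) / 8)
  views <- array(rep(view, 4), c(16, 16, 4))
  vol <- backProject(views, NULL, g, useCdr = FALSE, voxelSize = 1)
  rot90xy <- function(v) {
    out <- array(0, dim(v))
    for (k in seq_len(dim(v)[3])) out[, , k] <- t(v[, , k])[, dim(v)[1]:1]
    out
  }
  expect_lt(max(abs(vol - rot90xy(vol))), 1e-10)
})

test_that("scatter-window expectation matches its defining normalization", {
  ph <- phantom32()
  g <- geom32(8)
  pk <- forwardProject(ph@activity, ph@mu, g, voxelSize = 1.36)
  sc <- simulateScatter(ph@activity, ph@mu, g, fraction = 0.3,
                        voxelSize = 1.36, primary = pk)
  expect_equal(sum(sc) / sum(pk), 0.3, tolerance = 1e-6)
  z <- simulateScatter(array(0, dim(ph@mu)), ph@mu, g, voxelSize = 1.36)
  expect_true(all(z == 0))
  expect_error(simulateScatter(ph@activity, ph@mu, g, fraction = -1),
               ">= 0")
})

test_that("scatter views carry less high-frequency power than primary views", {
  ph <- phantom32()
  g <- geom32(8)
  ps <- projectPhantom(ph, g)
  hf <- function(img) {
    f <- Mod(stats::fft(img))^2
    fr <- slacspect:::fftFreq(nrow(img))
    hi <- sqrt(outer(fr^2, fr^2, `+`)) > 0.25 / 2   # above half-Nyquist
    sum(f[hi]) / sum(f)
  }
  pk <- ps@photopeak[, , 1] / sum(ps@photopeak[, , 1])
  sc <- ps@scatter[, , 1] / sum(ps@scatter[, , 1])
  expect_lte(hf(sc), hf(pk))
})

test_that("Poisson noise is seeded, unbiased, and has unit Fano factor", {
  g <- acquisitionGeometry(nAngles = 4, detectorBins = c(8, 8), binSize = 1)
  lam <- array(runif(8 * 8 * 4, 1, 4), c(8, 8, 4))
  ps <- projectionSet(g, lam)
  n1 <- addPoissonNoise(ps, 1e4, seed = 7)
  n2 <- addPoissonNoise(ps, 1e4, seed = 7)
  expect_identical(n1@photopeak, n2@photopeak)
  expect_true(n1@isNoisy)
  expect_true(all(n1@photopeak == round(n1@photopeak)))
  # law of large numbers on one bin over 1000 realizations
  s <- 1e4 / sum(lam)
  draws <- vapply(seq_len(1000), function(b)
    addPoissonNoise(ps, 1e4, seed = 100 + b)@photopeak[3, 3, 2], 0)
  expt <- s * lam[3, 3, 2]
  expect_lt(abs(mean(draws) - expt), 5 * sqrt(expt / 1000))
  fano <- var(draws) / mean(draws)
  expect_gt(fano, 0.85); expect_lt(fano, 1.15)
  expect_error(addPoissonNoise(ps, -5), "> 0")
})
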