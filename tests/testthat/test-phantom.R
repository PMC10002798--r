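test_that("defect catalog spans the full parameter grid in canonical order", {
  cat27 <- defectCatalog()
  expect_length(cat27, 27L)
  walls <- vapply(cat27, function(s) s@wall, "")
  extents <- vapply(cat27, function(s) s@extentDeg, 0)
  sevs <- vapply(cat27, function(s) s@severity, 0)
  expect_equal(sum(walls == "inferior"), 9L)
  expect_setequal(unique(sevs), c(0.10, 0.25, 0.50))
  expect_setequal(unique(extents), c(30, 60, 90))
  # ordering: wall, then extent, then severity, ascending
  expect_equal(walls, rep(c("anterior", "inferior", "lateral"), each = 9))
  expect_equal(extents[1:9], rep(c(30, 60, 90), each = 3))
  expect_equal(sevs[1:3], c(0.10, 0.25, 0.50))
  expect_equal(length(unique(vapply(cat27, function(s)
    paste(s@wall, s@extentDeg, s@severity), ""))), 27L)
})

test_that("phantom generation is a pure function of seed and parameters", {
  a <- generatePhantom(9, grid = grid32())
  b <- generatePhantom(9, grid = grid32())
  expect_identical(a@activity, b@activity)
  expect_identical(a@mu, b@mu)
  expect_identical(a@labels, b@labels)
  c <- generatePhantom(10, grid = grid32())
  expect_false(identical(a@activity, c@activity))
})

test_that("phantom anatomy satisfies its construction invariants", {
  ph <- phantom32()
  tb <- table(factor(ph@labels, levels = 0:5))
  expect_true(all(tb > 0))  # all six classes present
  expect_true(all(ph@activity >= 0))
  expect_true(all(ph@mu >= 0 & ph@mu <= 0.5))
  # attenuation ordering across classes
  ml <- function(cl) mean(ph@mu[ph@labels == cl])
  expect_lt(ml(3), ml(2))   # lungs < muscles/organs
  expect_lt(ml(2), ml(4))   # muscles/organs < bones
  # myocardial uptake at least 3x soft-tissue background
  shell <- ph@activity == max(ph@activity)
  expect_gte(max(ph@activity) / stats::median(ph@activity[ph@labels == 2]), 3)
  # no tracer outside the body
  expect_true(all(ph@activity[ph@labels %in% c(0L, 5L)] == 0))
})

test_that("phantom parameters outside their documented range are rejected", {
  expect_error(generatePhantom(1, params = phantomParams(bodyA = 30)),
               "bodyA")
  expect_error(generatePhantom(1, params = phantomParams(myoUptake = 1)),
               "myoUptake")
  expect_error(generatePhantom(-1), "seed")
})

test_that("defect insertion reduces exactly the in-sector activity", {
  ph <- phantom32()
  spec <- defectSpec(60, 0.50, "inferior")
  def <- insertDefect(ph, spec)
  expect_identical(def@mu, ph@mu)
  expect_identical(def@labels, ph@labels)
  changed <- def@activity != ph@activity
  expect_true(any(changed))
  # in-sector voxels exactly halved
  expect_equal(def@activity[changed], ph@activity[changed] / 2)

  # brute-force sector-membership oracle, voxel by voxel
  h <- ph@heart
  co <- coordArrays(ph@grid@shape, ph@grid@voxelSize)
  w <- h@axis
  u <- c(1, 0, 0) - sum(c(1, 0, 0) * w) * w; u <- u / sqrt(sum(u^2))
  v <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
         u[1] * w[2] - u[2] * w[1])
  idx <- which(ph@activity > 0)
  for (i in sample(idx, 500)) {
    p <- c(co$X[i], co$Y[i], co$Z[i]) - h@center
    t <- sum(p * w); pu <- sum(p * u); pv <- sum(p * v)
    rho2 <- pu^2 + pv^2
    inShell <- t >= 0 &&
      (rho2 / h@outerRadius^2 + t^2 / h@outerLength^2) <= 1 &&
      !((rho2 / h@innerRadius^2 + t^2 / h@innerLength^2) < 1)
    phi <- (atan2(pv, pu) * 180 / pi) %% 360
    dphi <- abs(((phi - h@wallAngles[["inferior"]] + 180) %% 360) - 180)
    inSector <- inShell && dphi <= 30
    expect_equal(unname(changed[i]), unname(inSector))
  }
})

test_that("degenerate severity-zero defect leaves the phantom unchanged", {
  ph <- phantom32()
  def <- insertDefect(ph, defectSpec(90, 0, "anterior"))
  expect_identical(def@activity, ph@activity)
})

test_that("modified-voxel count grows with defect extent", {
  ph <- phantom32()
  n <- vapply(c(30, 60, 90), function(e) {
    d <- insertDefect(ph, defectSpec(e, 0.25, "lateral"))
    sum(d@activity != ph@activity)
  }, 0)
  expect_lt(n[1], n[2])
  expect_lt(n[2], n[3])
})

test_that("defect insertion fails when the sector misses the myocardium", {
  ph <- phantom32()
  far <- heartGeometry(center = c(60, 60, 60), axis = c(0, 0, 1),
                       outerRadius = 2, innerRadius = 1)
  ph@heart <- far
  expect_error(insertDefect(ph, defectSpec(60, 0.25, "inferior")),
               "does not intersect")
})

test_that("pseudo-CT is the exact inverse-bilinear image of the mu map", {
  ph <- phantom32()
  hu <- simulatePseudoCT(ph, noiseSd = 0)
  expect_equal(max(abs(hu[ph@labels == 0L] - (-1000))), 0)
  # water-equivalent voxel maps to 0 HU
  model <- bilinearModel()
  expect_equal(muToHu(model@muWater, model), 0)
  # round trip recovers class mu to high precision
  back <- bilinearHuToMu(hu)
  expect_lt(max(abs(back - ph@mu)), 1e-6)
})

test_that("pseudo-CT noise is seeded and reproducible", {
  ph <- phantom32()
  expect_identical(simulatePseudoCT(ph, noiseSd = 15, seed = 3),
                   simulatePseudoCT(ph, noiseSd = 15, seed = 3))
})
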