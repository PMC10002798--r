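# Tiny synthetic slice task used for fast optimizer checks: the class is a
# deterministic function of smooth input patterns, so a small network can
# fit it.
tinyPairs <- function(n = 10L, size = 16L, seed = 21) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    cx <- runif(1, 6, 10); cy <- runif(1, 6, 10); r <- runif(1, 3, 5)
    g <- expand.grid(x = 1:size, y = 1:size)
    d2 <- (g$x - cx)^2 + (g$y - cy)^2
    lab <- matrix(0L, size, size)
    lab[d2 <= r^2] <- 2L
    lab[d2 <= (r / 2)^2] <- 3L
    lab[1:2, ] <- 1L; lab[, 1:2] <- 4L; lab[size, ] <- 5L
    inp <- array(c(matrix(exp(-d2 / r^2), size, size),
                   matrix(d2 / max(d2), size, size)), c(size, size, 2))
    list(input = inp, labels = lab)
  }))
}

test_that("network initialization follows its stated scheme", {
  net <- buildMcEUN(mceunConfig(baseFilters = 4), seed = 2)
  biases <- unlist(slacspect:::mapParams(function(x) x,
    list(enc = lapply(net$params$enc, `[[`, "b"))))
  expect_true(all(biases == 0.03))
  # every bias in the whole tree is 0.03
  allB <- c(unlist(lapply(net$params$enc, `[[`, "b")),
            unlist(lapply(net$params$dec, function(d) c(
              d$out$b, unlist(lapply(d$lev, function(l)
                c(l$ag$bq, l$ag$bPsi, l$conv$b)))))))
  expect_true(all(allB == 0.03))
  # Glorot-normal weights: zero-centered, scale shrinks with fan-in
  w1 <- net$params$enc[[1]]$W; w3 <- net$params$enc[[3]]$W
  expect_lt(abs(mean(w1)), 0.05)
  expect_lt(sd(w3), sd(w1))
  # identical seeds give identical networks
  expect_identical(net$params, buildMcEUN(mceunConfig(baseFilters = 4),
                                          seed = 2)$params)
})

test_that("forward pass yields voxelwise probabilities over six heads", {
  net <- buildMcEUN(mceunConfig(baseFilters = 4), seed = 3)
  x <- array(withr::with_seed(4, rnorm(16 * 16 * 2)), c(16, 16, 2))
  f <- slacspect:::mceunForward(net, x)
  expect_identical(dim(f$prob), c(16L, 16L, 6L))
  sums <- apply(f$prob, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  # dropout disabled at inference: deterministic
  f2 <- slacspect:::mceunForward(net, x)
  expect_identical(f$prob, f2$prob)
  expect_error(slacspect:::mceunForward(net, array(0, c(12, 12, 2))),
               "divisible")
})

test_that("analytic gradients match finite differences", {
  cfg <- mceunConfig(inChannels = 2, depth = 2, baseFilters = 2, dropout = 0)
  net <- buildMcEUN(cfg, seed = 3)
  x <- array(withr::with_seed(5, rnorm(8 * 8 * 2)), c(8, 8, 2))
  y <- matrix(withr::with_seed(6, sample(0:5, 64, TRUE)), 8, 8)
  w <- rep(1, 6)
  f <- slacspect:::mceunForward(net, x, train = TRUE)
  lo <- slacspect:::mceunLoss(f$prob, y, w)
  g <- slacspect:::mceunBackward(net, f, lo$dscore)
  lossAt <- function(params) {
    n2 <- net; n2$params <- params
    f2 <- slacspect:::mceunForward(n2, x)
    slacspect:::mceunLoss(f2$prob, y, w)$loss
  }
  getP <- function(pp, path) {for (k in path) pp <- pp[[k]]; pp}
  setP <- function(pp, path, v) {
    if (length(path) == 1) {pp[[path[[1]]]] <- v; return(pp)}
    pp[[path[[1]]]] <- setP(pp[[path[[1]]]], path[-1], v); pp
  }
  paths <- list(list("enc", 1L, "W"), list("enc", 2L, "b"),
                list("dec", 1L, "out", "W"),
                list("dec", 4L, "lev", "1", "conv", "W"),
                list("dec", 4L, "lev", "1", "ag", "Wx"),
                list("dec", 4L, "lev", "1", "ag", "Wg"),
                list("dec", 4L, "lev", "1", "ag", "Psi"))
  eps <- 1e-6
  for (path in paths) {
    base <- getP(net$params, path)
    for (i in seq_len(min(3, length(base)))) {
      v1 <- base; v1[i] <- v1[i] + eps
      v2 <- base; v2[i] <- v2[i] - eps
      num <- (lossAt(setP(net$params, path, v1)) -
              lossAt(setP(net$params, path, v2))) / (2 * eps)
      ana <- getP(g, path)[i]
      expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("training reduces the loss and is bit-reproducible", {
  pairs <- tinyPairs()
  net <- buildMcEUN(mceunConfig(depth = 2, baseFilters = 4, dropout = 0.05),
                    seed = 7)
  r1 <- trainMcEUN(net, pairs, epochs = 20, batchSize = 5, seed = 8,
                   cv = FALSE)
  lg <- r1$log$log
  expect_lt(lg$trainLoss[20], lg$trainLoss[1])
  r2 <- trainMcEUN(net, pairs, epochs = 20, batchSize = 5, seed = 8,
                   cv = FALSE)
  expect_identical(r1$net$params, r2$net$params)
})

test_that("cross-validation folds partition the training set evenly", {
  pairs <- tinyPairs(20)
  net <- buildMcEUN(mceunConfig(depth = 2, baseFilters = 2), seed = 7)
  res <- trainMcEUN(net, pairs, epochs = 1, batchSize = 10, seed = 9,
                    cv = TRUE, cvEpochs = 1)
  folds <- res$log$folds
  expect_length(folds, 20L)
  expect_equal(unname(as.vector(table(folds))), rep(4L, 5))
  cvLog <- res$log$log[res$log$log$phase == "cv", ]
  expect_equal(sort(unique(cvLog$fold)), 1:5)
  expect_true(all(is.finite(cvLog$valLoss[!is.na(cvLog$valLoss)])))
  expect_error(trainMcEUN(net, pairs[1:3], folds = 5), "folds")
})

test_that("a class absent from every target is an error", {
  pairs <- tinyPairs()
  pairs <- lapply(pairs, function(p) {
    p$labels[p$labels == 3L] <- 2L
    p
  })
  expect_error(slacspect:::inverseFrequencyWeights(pairs), "lungs")
})

test_that("predicted labels are the voxelwise arg-max over the six heads", {
  net <- buildMcEUN(mceunConfig(baseFilters = 4), seed = 11)
  vol <- array(withr::with_seed(12, runif(16 * 16 * 4)), c(16, 16, 4))
  vol <- vol / mean(vol[vol > 0])
  pred <- suppressWarnings(predictSegmentation(net, vol, vol))
  expect_true(all(pred %in% 0:5))
  # brute-force per-voxel maximum over heads on one slice
  x <- array(c(vol[, , 2], vol[, , 2]), c(16, 16, 2))
  f <- slacspect:::mceunForward(net, x)
  manual <- apply(f$prob, c(1, 2), which.max) - 1L
  expect_identical(pred[, , 2], manual)
  # unnormalized input triggers a warning
  expect_warning(predictSegmentation(net, vol * 50, vol), "normalized")
})

test_that("trained network segments held-out phantoms", {
  # desk-scale training: six training phantoms, two held out, slice mode
  grid <- grid32()
  g <- geom32(16)
  mk <- function(seeds) lapply(seeds, function(s) {
    ph <- generatePhantom(s, grid = grid)
    noisy <- addPoissonNoise(projectPhantom(ph, g), 2e6, seed = s)
    init <- reconstructInitialEstimates(noisy,
      scatterConfig = reconConfig(4, 5, useAttenuation = FALSE),
      photoConfig = reconConfig(4, 3, useAttenuation = FALSE))
    list(ph = ph, init = init)
  })
  train <- mk(1:6)
  pairs <- list()
  for (tr in train) for (k in seq(6, 27, by = 3))
    pairs[[length(pairs) + 1]] <- list(
      input = array(c(tr$init$scatter[, , k], tr$init$photopeak[, , k]),
                    c(32, 32, 2)),
      labels = tr$ph@labels[, , k])
  net <- buildMcEUN(mceunConfig(baseFilters = 8, depth = 3, dropout = 0.1),
                    seed = 5)
  res <- trainMcEUN(net, pairs, epochs = 20, batchSize = 8, seed = 6,
                    cv = FALSE)
  dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
  for (te in mk(21:22)) {
    pred <- predictSegmentation(res$net, te$init$scatter, te$init$photopeak)
    expect_gte(dice(pred == 3L, te$ph@labels == 3L), 0.80)          # lungs
    body <- function(l) l > 0L & l != 5L
    expect_gte(dice(body(pred), body(te$ph@labels)), 0.80)          # body
  }
})

test_that("the classical fallback segmenter recovers all six classes", {
  fx <- initEstimates64()
  seg <- classicalFallbackSegment(fx$init$scatter, fx$init$photopeak)
  expect_gte(mean(seg == fx$phantom@labels), 0.85)
  expect_true(all(0:5 %in% unique(as.vector(seg))))
  # deterministic
  seg2 <- classicalFallbackSegment(fx$init$scatter, fx$init$photopeak)
  expect_identical(seg, seg2)
  # consumable by assignMu
  tm <- fitTissueModel(list(fx$phantom@mu), list(fx$phantom@labels))
  expect_silent(assignMu(seg, tm))
})
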