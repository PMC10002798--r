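test_that("the channel bank realizes disjoint rotationally symmetric bands", {
  bank <- makeChannelBank()
  expect_identical(dim(bank@channels), c(1024L, 4L))
  # disjoint frequency bands give orthonormal spatial templates
  gram <- crossprod(bank@channels)
  expect_lt(max(abs(gram - diag(4))), 1e-10)
  # responses are invariant under exact 90-degree grid rotations
  img <- matrix(withr::with_seed(1, rnorm(1024)), 32)
  n <- 32L; c0 <- n / 2 + 1
  rot90c <- function(im) {      # circular rotation about the DFT center
    out <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      ii <- ((j - c0) + c0 - 1) %% n + 1
      jj <- ((-(i - c0)) + c0 - 1) %% n + 1
      out[i, j] <- im[ii, jj]
    }
    out
  }
  r1 <- crossprod(bank@channels, as.vector(img))
  r2 <- crossprod(bank@channels, as.vector(rot90c(img)))
  expect_lt(max(abs(r1 - r2)), 1e-6)
  expect_error(makeChannelBank(nChannels = 2,
                               edges = cbind(c(0.01, 0.02), c(0.03, 0.04))),
               "overlap")
  expect_error(makeChannelBank(imageSize = 31), "even")
})

test_that("CHO leave-one-out equals the brute-force per-image refit", {
  bank <- makeChannelBank()
  imgs <- array(withr::with_seed(3, rnorm(32 * 32 * 24)), c(32, 32, 24))
  lab <- rep(0:1, each = 12)
  imgs[, , lab == 1] <- imgs[, , lab == 1] + 0.1
  st <- choScores(imgs, lab, bank, leaveOneOut = TRUE)
  V <- channelize(imgs, bank)
  brute <- vapply(1:24, function(i) {
    Vi <- V[, -i]; li <- lab[-i]
    m0 <- rowMeans(Vi[, li == 0]); m1 <- rowMeans(Vi[, li == 1])
    Vc <- Vi
    Vc[, li == 0] <- Vi[, li == 0] - m0
    Vc[, li == 1] <- Vi[, li == 1] - m1
    S <- tcrossprod(Vc) / (23 - 2)
    Sr <- S + diag(1e-6 * sum(diag(S)) / 4, 4)
    sum(solve(Sr, m1 - m0) * V[, i])
  }, 0)
  expect_equal(st, brute, tolerance = 1e-10)
  expect_error(choScores(imgs[, , 1:3], c(0, 0, 1), bank), "at least 2")
})

test_that("CHO attains the closed-form Hotelling AUC on Gaussian channels", {
  bank <- makeChannelBank()
  nc <- 4; n <- 500
  dmu <- c(0.5, 0.3, 0.2, 0.1)
  snr <- sqrt(sum(dmu^2))
  withr::with_seed(2, {
    v0 <- matrix(rnorm(nc * n), nc)
    v1 <- matrix(rnorm(nc * n), nc) + dmu
  })
  # synthesize images whose channel responses are exactly v (orthonormal T)
  imgs <- array(cbind(bank@channels %*% v0, bank@channels %*% v1),
                c(32, 32, 2 * n))
  lab <- rep(0:1, each = n)
  st <- choScores(imgs, lab, bank)
  auc <- empiricalRocAuc(st, lab, nBoot = 0)$auc
  expect_equal(auc, pnorm(snr / sqrt(2)), tolerance = 0.03)
})

test_that("null-distribution CHO scores give chance-level AUC", {
  bank <- makeChannelBank()
  imgs <- array(withr::with_seed(5, rnorm(32 * 32 * 400)), c(32, 32, 400))
  lab <- rep(0:1, each = 200)
  st <- choScores(imgs, lab, bank)
  auc <- empiricalRocAuc(st, lab, nBoot = 0)$auc
  expect_gte(auc, 0.4); expect_lte(auc, 0.6)
})

test_that("empirical AUC is the pairwise-comparison statistic", {
  s <- c(0.1, 0.4, 0.4, 0.9, 1.2, 0.2)
  l <- c(0, 0, 1, 1, 1, 0)
  res <- empiricalRocAuc(s, l, nBoot = 100, seed = 1)
  # brute-force count over all present/absent pairs, ties half
  cnt <- 0
  for (i in which(l == 1)) for (j in which(l == 0))
    cnt <- cnt + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  expect_equal(res$auc, cnt / (sum(l == 1) * sum(l == 0)))
  # ROC endpoints
  expect_equal(res$roc$fpf[1], 0); expect_equal(res$roc$tpf[1], 0)
  expect_equal(res$roc$fpf[nrow(res$roc)], 1)
  expect_equal(res$roc$tpf[nrow(res$roc)], 1)
  expect_true(res$ci[1] <= res$auc && res$ci[2] >= res$auc)
  # perfectly separated and null cases
  expect_equal(empiricalRocAuc(c(1, 2, 3, 4), c(0, 0, 1, 1),
                               nBoot = 0)$auc, 1)
  st <- withr::with_seed(6, rnorm(400))
  expect_equal(empiricalRocAuc(st, rep(0:1, 200), nBoot = 0)$auc, 0.5,
               tolerance = 0.1)
  expect_error(empiricalRocAuc(c(1, 2), c(1, 1)), "both classes")
})

test_that("empirical AUC is invariant under strictly monotone transforms", {
  withr::with_seed(7, {
    s <- rnorm(100)
    l <- rbinom(100, 1, 0.5)
  })
  l[1:2] <- c(0, 1)
  a1 <- empiricalRocAuc(s, l, nBoot = 0)$auc
  expect_equal(empiricalRocAuc(exp(s), l, nBoot = 0)$auc, a1)
  expect_equal(empiricalRocAuc(2 * s - 7, l, nBoot = 0)$auc, a1)
})

test_that("bootstrap CI width shrinks with sample size", {
  gen <- function(n, seed) withr::with_seed(seed,
    list(s = c(rnorm(n), rnorm(n, 1)), l = rep(0:1, each = n)))
  d50 <- gen(50, 8); d500 <- gen(500, 9)
  w50 <- diff(empiricalRocAuc(d50$s, d50$l, nBoot = 400, seed = 1)$ci)
  w500 <- diff(empiricalRocAuc(d500$s, d500$l, nBoot = 400, seed = 1)$ci)
  expect_lt(w500, w50)
})

test_that("binormal fit recovers simulated parameters", {
  withr::with_seed(4, {
    s0 <- rnorm(500); s1 <- rnorm(500, 1.5, 1)
  })
  fit <- binormalFit(c(s0, s1), rep(0:1, each = 500))
  expect_true(fit$converged)
  expect_lt(abs(fit$a - 1.5), 0.2)
  expect_lt(abs(fit$auc - pnorm(1.5 / sqrt(2))), 0.03)
})

test_that("binormal fit is near chance for identical class distributions", {
  st <- withr::with_seed(10, rnorm(400))
  fit <- binormalFit(st, rep(0:1, 200))
  expect_lt(abs(fit$auc - 0.5), 0.05)
})

test_that("a symmetric binormal ROC is concave from (0,0) to (1,1)", {
  withr::with_seed(11, {
    s0 <- rnorm(300); s1 <- rnorm(300, 1.2, 1)   # b = 1 case
  })
  fit <- binormalFit(c(s0, s1), rep(0:1, each = 300))
  expect_true(fit$converged)
  x <- seq(0, 1, by = 0.01)
  y <- pnorm(fit$a + fit$b * qnorm(x))
  expect_equal(y[1], 0); expect_equal(y[length(y)], 1)
  expect_true(all(diff(y, differences = 2) < 1e-8))  # concave
})

test_that("fidelity metrics match their definitions", {
  v <- array(withr::with_seed(12, runif(8^3)), c(8, 8, 8))
  self <- fidelityMetrics(v, v)
  expect_equal(unname(self["rmse"]), 0)
  expect_equal(unname(self["ssim"]), 1)
  off <- fidelityMetrics(v + 0.2, v, normalize = FALSE)
  expect_equal(unname(off["rmse"]), 0.2, tolerance = 1e-12)
  expect_error(fidelityMetrics(v, array(0, dim(v))), "all-zero")
  expect_error(fidelityMetrics(v, array(1, c(4, 4, 4))), "shape")
})

test_that("SSIM agrees with a direct reimplementation of the formula", {
  withr::with_seed(13, {
    x <- array(runif(8^3), c(8, 8, 8))
    y <- x + array(rnorm(8^3, 0, 0.05), c(8, 8, 8))
  })
  got <- fidelityMetrics(y, x)["ssim"]
  # independent oracle: explicit Gaussian-window loops, zero padding
  sc <- max(x); xs <- x / sc; ys <- y / sc
  k <- slacspect:::gaussKernel1d(1.5)
  r <- (length(k) - 1) / 2
  w3 <- array(0, c(length(k), length(k), length(k)))
  for (a in seq_along(k)) for (b in seq_along(k)) for (cc in seq_along(k))
    w3[a, b, cc] <- k[a] * k[b] * k[cc]
  wmean <- function(v, i, j, l) {
    acc <- 0
    for (a in -r:r) for (b in -r:r) for (cc in -r:r) {
      ii <- i + a; jj <- j + b; ll <- l + cc
      if (ii >= 1 && ii <= 8 && jj >= 1 && jj <= 8 && ll >= 1 && ll <= 8)
        acc <- acc + w3[a + r + 1, b + r + 1, cc + r + 1] * v[ii, jj, ll]
    }
    acc
  }
  C1 <- 0.01^2; C2 <- 0.03^2
  vals <- numeric(8^3); t <- 0
  for (l in 1:8) for (j in 1:8) for (i in 1:8) {
    mx <- wmean(xs, i, j, l); my <- wmean(ys, i, j, l)
    sxx <- wmean(xs^2, i, j, l) - mx^2
    syy <- wmean(ys^2, i, j, l) - my^2
    sxy <- wmean(xs * ys, i, j, l) - mx * my
    t <- t + 1
    vals[t] <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
               ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  }
  expect_equal(unname(got), mean(vals), tolerance = 1e-6)
})
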