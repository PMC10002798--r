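#' Rotationally symmetric frequency-channel bank
#'
#' Square-profile octave bands in radial spatial frequency, realized as
#' indicator functions on the DFT grid, inverse-transformed to spatial
#' templates (centered on the image), and unit-normalized. Defaults are the
#' four octave bands (1/64, 1/32], (1/32, 1/16], (1/16, 1/8], (1/8, 1/4]
#' cycles/pixel; bands are right-closed so the lowest band contains the
#' fundamental frequency of a 32-pixel ROI.
#'
#' @param imageSize even ROI side in pixels (default 32)
#' @param nChannels number of octave channels (default 4)
#' @param edges optional `[nChannels, 2]` matrix of band edges
#'   (cycles/pixel); bands must not overlap
#' @return A [ChannelBank-class].
#' @export
#' @examples
#' dim(makeChannelBank()@channels)
makeChannelBank <- function(imageSize = 32L, nChannels = 4L, edges = NULL) {
  if (imageSize %% 2 != 0) stop("imageSize must be even")
  if (is.null(edges)) {
    lo <- 1 / 64 * 2^(seq_len(nChannels) - 1)
    edges <- cbind(lo, 2 * lo)
  }
  edges <- as.matrix(edges)
  if (nrow(edges) != nChannels) stop("edges must have nChannels rows")
  o <- order(edges[, 1])
  e <- edges[o, , drop = FALSE]
  if (any(e[, 2] <= e[, 1]) ||
      (nrow(e) > 1 && any(e[-1, 1] < e[-nrow(e), 2] - 1e-12)))
    stop("channel bands must be non-overlapping")
  fx <- fftFreq(imageSize)
  r <- sqrt(outer(fx^2, fx^2, `+`))
  ch <- matrix(0, imageSize^2, nChannels)
  shift <- (-1)^(outer(seq_len(imageSize) - 1, seq_len(imageSize) - 1, `+`))
  for (k in seq_len(nChannels)) {
    ind <- (r > edges[k, 1] & r <= edges[k, 2]) * 1
    tpl <- Re(fft(ind * shift, inverse = TRUE)) / imageSize^2
    nrm <- sqrt(sum(tpl^2))
    if (nrm == 0) stop("channel ", k, " is empty on this grid")
    ch[, k] <- as.vector(tpl) / nrm
  }
  new("ChannelBank", imageSize = as.integer(imageSize), edges = edges,
      channels = ch)
}

#' Channelize a set of ROI images
#'
#' @param images array `[size, size, n]` or list of matrices
#' @param bank a [ChannelBank-class]
#' @return Matrix `[nChannels, n]` of channel responses.
#' @export
channelize <- function(images, bank) {
  if (is.list(images)) images <- simplify2array(images)
  if (length(dim(images)) == 2) images <- array(images, c(dim(images), 1))
  n <- dim(images)[3]
  X <- matrix(images, bank@imageSize^2, n)
  t(bank@channels) %*% X
}

#' Channelized Hotelling observer test statistics
#'
#' Linear Hotelling observer in channel space: with class means and the
#' pooled within-class channel covariance, each image's statistic is
#' `t = (mu1 - mu0)' S^-1 v`. With `leaveOneOut = TRUE` (the default) the
#' means and covariance for image i are estimated from all other images,
#' using exact rank-one downdates of the class means and pooled scatter.
#' The covariance is ridge-regularized by
#' `ridge * trace(S) / nChannels` for numerical stability.
#'
#' @param images array `[size, size, n]` or list of ROI matrices
#' @param labels integer 0/1 vector (1 = defect present)
#' @param bank a [ChannelBank-class]
#' @param leaveOneOut use the leave-one-out strategy?
#' @param ridge relative ridge (default 1e-6)
#' @return Numeric vector of per-image test statistics.
#' @export
choScores <- function(images, labels, bank = makeChannelBank(),
                      leaveOneOut = TRUE, ridge = 1e-6) {
  V <- channelize(images, bank)
  labels <- as.integer(labels)
  n <- ncol(V); nc <- nrow(V)
  if (length(labels) != n) stop("one label per image required")
  n0 <- sum(labels == 0); n1 <- sum(labels == 1)
  if (min(n0, n1) < 2) stop("need at least 2 images per class")
  m0 <- rowMeans(V[, labels == 0, drop = FALSE])
  m1 <- rowMeans(V[, labels == 1, drop = FALSE])
  Vc <- V
  Vc[, labels == 0] <- V[, labels == 0] - m0
  Vc[, labels == 1] <- V[, labels == 1] - m1
  W <- tcrossprod(Vc)  # pooled within-class scatter
  solveRidge <- function(S, x) {
    Sr <- S + diag(ridge * sum(diag(S)) / nc, nc)
    out <- tryCatch(solve(Sr, x), error = function(e) NULL)
    if (is.null(out)) stop("singular channel covariance after ridge")
    out
  }
  if (!leaveOneOut) {
    S <- W / (n - 2)
    w <- solveRidge(S, m1 - m0)
    return(as.vector(crossprod(w, V)))
  }
  stats <- numeric(n)
  for (i in seq_len(n)) {
    v <- V[, i]
    if (labels[i] == 0) {
      m0i <- (n0 * m0 - v) / (n0 - 1); m1i <- m1
      dv <- v - m0
      Wi <- W - (n0 / (n0 - 1)) * tcrossprod(dv)
    } else {
      m1i <- (n1 * m1 - v) / (n1 - 1); m0i <- m0
      dv <- v - m1
      Wi <- W - (n1 / (n1 - 1)) * tcrossprod(dv)
    }
    Si <- Wi / (n - 3)
    stats[i] <- sum(solveRidge(Si, m1i - m0i) * v)
  }
  stats
}

#' Empirical ROC curve, AUC and bootstrap confidence interval
#'
#' The AUC is the Mann-Whitney statistic (probability that a defect-present
#' statistic exceeds a defect-absent one, ties counted one half); the 95%
#' CI is a class-stratified nonparametric percentile bootstrap over images.
#'
#' @param statistics per-image test statistics
#' @param labels integer 0/1 truth
#' @param nBoot bootstrap replicates (default 1000; 0 disables the CI)
#' @param seed bootstrap seed
#' @return List with `roc` (data.frame fpf/tpf), `auc`, and `ci`
#'   (numeric(2)).
#' @export
empiricalRocAuc <- function(statistics, labels, nBoot = 1000L, seed = 1) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  aucOf <- function(s, l) {
    r <- rank(s)
    n1 <- sum(l == 1); n0 <- sum(l == 0)
    (sum(r[l == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  }
  auc <- aucOf(statistics, labels)
  thr <- c(Inf, sort(unique(statistics), decreasing = TRUE))
  fpf <- vapply(thr, function(t) mean(statistics[labels == 0] >= t),
                numeric(1))
  tpf <- vapply(thr, function(t) mean(statistics[labels == 1] >= t),
                numeric(1))
  ci <- c(NA_real_, NA_real_)
  if (nBoot > 0) {
    i0 <- which(labels == 0); i1 <- which(labels == 1)
    boot <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
      idx <- c(sample(i0, replace = TRUE), sample(i1, replace = TRUE))
      aucOf(statistics[idx], labels[idx])
    }, numeric(1)))
    ci <- unname(quantile(boot, c(0.025, 0.975)))
    ci <- c(min(ci[1], auc), max(ci[2], auc))
  }
  list(roc = data.frame(fpf = fpf, tpf = tpf), auc = auc, ci = ci)
}

#' Maximum-likelihood binormal ROC fit for continuous ratings
#'
#' Conventional binormal model: defect-absent latent decision variables are
#' N(0, 1) and defect-present ones N(a/b, 1/b) on that scale, so
#' `TPF = Phi(a + b * Phi^-1(FPF))` and the fitted
#' `AUC = Phi(a / sqrt(1 + b^2))`. Continuous ratings are discretized into
#' runs of the ordered data (categories bounded where the truth state
#' changes), merged to at most `maxBins` categories, and the category model
#' is fit by maximum likelihood over (a, b, cutpoints). If the optimizer
#' fails or the fit degenerates, the result is flagged and the empirical
#' AUC is reported instead.
#'
#' @param statistics per-image ratings
#' @param labels integer 0/1 truth (>= 10 per class recommended)
#' @param maxBins maximum number of rating categories (default 20)
#' @return List with `a`, `b`, `auc`, `converged`.
#' @export
binormalFit <- function(statistics, labels, maxBins = 20L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  ord <- order(statistics)
  l <- labels[ord]
  runId <- cumsum(c(1L, diff(l) != 0L))
  # merge smallest adjacent runs down to maxBins categories
  counts <- as.vector(table(runId))
  while (length(counts) > maxBins) {
    k <- which.min(counts[-1] + counts[-length(counts)])
    counts[k] <- counts[k] + counts[k + 1]
    counts <- counts[-(k + 1)]
  }
  cat_ <- rep(seq_along(counts), counts)
  K <- length(counts)
  n0k <- vapply(seq_len(K), function(k) sum(l[cat_ == k] == 0), numeric(1))
  n1k <- vapply(seq_len(K), function(k) sum(l[cat_ == k] == 1), numeric(1))

  s0 <- statistics[labels == 0]; s1 <- statistics[labels == 1]
  empAuc <- empiricalRocAuc(statistics, labels, nBoot = 0)$auc
  fallback <- list(a = NA_real_, b = NA_real_, auc = empAuc,
                   converged = FALSE)
  if (K < 3 || sd(s0) == 0 || sd(s1) == 0) return(fallback)

  bInit <- sd(s0) / sd(s1)
  aInit <- (mean(s1) - mean(s0)) / sd(s1)
  # cutpoints on the noise scale: standardized run boundaries
  bounds <- vapply(seq_len(K - 1), function(k)
    max(statistics[ord][cat_ <= k]), numeric(1))
  cInit <- (bounds - mean(s0)) / sd(s0)
  cInit <- cummax(cInit + seq_len(K - 1) * 1e-9)
  theta0 <- c(aInit, log(max(bInit, 1e-3)), cInit[1],
              log(pmax(diff(cInit), 1e-6)))

  negll <- function(theta) {
    a <- theta[1]; b <- exp(theta[2])
    cuts <- cumsum(c(theta[3], exp(theta[-(1:3)])))
    p0 <- diff(c(0, pnorm(cuts), 1))
    p1 <- diff(c(0, pnorm(b * cuts - a), 1))
    -sum(n0k * log(pmax(p0, 1e-12)) + n1k * log(pmax(p1, 1e-12)))
  }
  fit <- tryCatch(optim(theta0, negll, method = "BFGS",
                        control = list(maxit = 500)),
                  error = function(e) NULL)
  if (is.null(fit)) return(fallback)
  a <- fit$par[1]; b <- exp(fit$par[2])
  if (fit$convergence != 0 || !is.finite(a) || abs(a) > 10 ||
      b < 0.05 || b > 20) return(fallback)
  list(a = a, b = b, auc = pnorm(a / sqrt(1 + b^2)), converged = TRUE)
}

#' Fidelity metrics: RMSE and SSIM
#'
#' Root mean-square error and mean structural similarity between a test
#' volume and a reference volume (the CT-compensated image in the
#' evaluation pipeline). With `normalize = TRUE` both volumes are divided
#' by the reference maximum, and SSIM uses the standard constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` on that unit dynamic range with a
#' Gaussian window (sigma 1.5 voxels).
#'
#' @param test,reference arrays of identical shape
#' @param normalize divide both volumes by `max(reference)`?
#' @return Named numeric: `rmse`, `ssim`.
#' @export
fidelityMetrics <- function(test, reference, normalize = TRUE) {
  if (!identical(dim(test), dim(reference)))
    stop("volumes must share a shape")
  if (all(reference == 0)) stop("all-zero reference")
  if (normalize) {
    sc <- max(reference)
    test <- test / sc; reference <- reference / sc
    L <- 1
  } else L <- max(reference) - min(reference)
  rmse <- sqrt(mean((test - reference)^2))
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  blur <- function(v) gaussSmooth3d(v, 1.5)
  mx <- blur(test); my <- blur(reference)
  sxx <- blur(test^2) - mx^2
  syy <- blur(reference^2) - my^2
  sxy <- blur(test * reference) - mx * my
  ssim <- mean(((2 * mx * my + C1) * (2 * sxy + C2)) /
               ((mx^2 + my^2 + C1) * (sxx + syy + C2)))
  c(rmse = rmse, ssim = ssim)
}
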