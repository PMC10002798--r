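#' McEUN configuration
#'
#' Architecture of the multi-channel-input, multi-decoder attention-gated
#' U-Net that segments the transmission-less initial estimates into six
#' tissue classes: one shared encoder reading the stacked (scatter-window,
#' photopeak) reconstructions, and six decoders (one per class) whose skip
#' connections pass through additive attention gates. Applied slice-by-slice
#' along the scanner axis.
#'
#' @param inChannels input channels (default 2: scatter-window NAC
#'   reconstruction, photopeak NAC reconstruction)
#' @param depth encoder levels (>= 2; `depth - 1` poolings)
#' @param baseFilters filters at the finest level (doubled per level)
#' @param dropout dropout rate applied at the bottleneck during training
#' @param biasInit constant bias initialization (0.03)
#' @param classWeights optional 6-vector of cross-entropy weights
#' @return List of class `"McEUNConfig"`.
#' @export
mceunConfig <- function(inChannels = 2L, depth = 3L, baseFilters = 8L,
                        dropout = 0.1, biasInit = 0.03, classWeights = NULL) {
  stopifnot(depth >= 2, dropout >= 0, dropout < 1, inChannels >= 1)
  structure(list(inChannels = as.integer(inChannels), depth = as.integer(depth),
                 baseFilters = as.integer(baseFilters), dropout = dropout,
                 biasInit = biasInit, classWeights = classWeights,
                 nClasses = 6L),
            class = "McEUNConfig")
}

glorot <- function(fanIn, fanOut, nIn, nOut) {
  matrix(rnorm(nIn * nOut, 0, sqrt(2 / (fanIn + fanOut))), nIn, nOut)
}

#' Build an initialized McEUN
#'
#' Kernel weights use the Glorot-normal initializer; every bias is the
#' constant 0.03. The returned network is a plain parameter container; with
#' dropout disabled the forward pass is deterministic.
#'
#' @param config an [mceunConfig()] list
#' @param seed seed for weight initialization
#' @return List of class `"McEUN"` with elements `config` and `params`.
#' @export
buildMcEUN <- function(config = mceunConfig(), seed = 1) {
  cfg <- config
  ec <- cfg$baseFilters * 2^(seq_len(cfg$depth) - 1)
  withSeed(seed, {
    b0 <- cfg$biasInit
    enc <- vector("list", cfg$depth)
    cin <- cfg$inChannels
    for (l in seq_len(cfg$depth)) {
      enc[[l]] <- list(W = glorot(9 * cin, 9 * ec[l], 9 * cin, ec[l]),
                       b = rep(b0, ec[l]))
      cin <- ec[l]
    }
    dec <- lapply(seq_len(cfg$nClasses), function(h) {
      lev <- list()
      for (l in seq(cfg$depth - 1, 1)) {
        cSkip <- ec[l]; cGate <- ec[l + 1]; ci <- ec[l]
        lev[[as.character(l)]] <- list(
          ag = list(Wx = glorot(cSkip, ci, cSkip, ci),
                    Wg = glorot(cGate, ci, cGate, ci),
                    bq = rep(b0, ci),
                    Psi = glorot(ci, 1, ci, 1), bPsi = b0),
          conv = list(W = glorot(9 * (cGate + cSkip), 9 * ec[l],
                                 9 * (cGate + cSkip), ec[l]),
                      b = rep(b0, ec[l])))
      }
      list(lev = lev, out = list(W = glorot(ec[1], 1, ec[1], 1), b = b0))
    })
    structure(list(config = cfg, params = list(enc = enc, dec = dec)),
              class = "McEUN")
  })
}

#' @export
print.McEUN <- function(x, ...) {
  cfg <- x$config
  np <- sum(unlist(mapParams(length, x$params)))
  cat("McEUN segmenter: depth", cfg$depth, "| base filters", cfg$baseFilters,
      "|", cfg$inChannels, "input channels | 6 attention-gated decoders |",
      np, "parameters\n")
  invisible(x)
}

# Forward pass on one [H, W, inChannels] slice. Returns per-class
# probabilities and (optionally) every cache needed for the backward pass.
mceunForward <- function(net, x, train = FALSE, keepCache = train) {
  cfg <- net$config; P <- net$params
  d <- dim(x)
  if (d[1] %% 2^cfg$depth != 0 || d[2] %% 2^cfg$depth != 0)
    stop("input shape must be divisible by 2^depth")
  encA <- list(); encPre <- list(); pools <- list(); cols <- list()
  cur <- x
  for (l in seq_len(cfg$depth)) {
    cv <- convFwd(cur, P$enc[[l]]$W, P$enc[[l]]$b)
    encPre[[l]] <- cv$y; cols[[l]] <- cv$cols
    encA[[l]] <- reluFwd(cv$y)
    if (l < cfg$depth) {
      pools[[l]] <- maxpoolFwd(encA[[l]])
      cur <- pools[[l]]$y
    }
  }
  bott <- encA[[cfg$depth]]
  dropMask <- NULL
  if (train && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    dropMask <- array(runif(length(bott)) < keep, dim(bott)) / keep
    bott <- bott * dropMask
  }
  heads <- vector("list", cfg$nClasses)
  scores <- array(0, c(d[1], d[2], cfg$nClasses))
  for (h in seq_len(cfg$nClasses)) {
    hp <- P$dec[[h]]
    hc <- list(lev = list())
    cur <- bott
    for (l in seq(cfg$depth - 1, 1)) {
      lp <- hp$lev[[as.character(l)]]
      g <- upsampleFwd(cur)
      ag <- agFwd(encA[[l]], g, lp$ag)
      cat_ <- array(c(g, ag$y), c(dim(g)[1], dim(g)[2],
                                  dim(g)[3] + dim(ag$y)[3]))
      cv <- convFwd(cat_, lp$conv$W, lp$conv$b)
      act <- reluFwd(cv$y)
      if (keepCache)
        hc$lev[[as.character(l)]] <- list(g = g, ag = ag, cat = cat_,
                                          pre = cv$y, cols = cv$cols,
                                          curIn = cur)
      cur <- act
    }
    sc <- conv1Fwd(cur, hp$out$W, hp$out$b)
    if (keepCache) hc$final <- cur
    scores[, , h] <- sc[, , 1]
    heads[[h]] <- hc
  }
  sm <- asMat(scores)
  sm <- sm - apply(sm, 1, max)
  es <- exp(sm)
  p <- es / rowSums(es)
  res <- list(prob = array(p, dim(scores)), scores = scores)
  if (keepCache)
    res$cache <- list(encA = encA, encPre = encPre, pools = pools,
                      cols = cols, heads = heads, dropMask = dropMask,
                      x = x)
  res
}

# Weighted cross-entropy loss and gradient at the score maps.
# labels: [H, W] integers 0..5; w: numeric(6) class weights.
mceunLoss <- function(prob, labels, w) {
  pm <- asMat(prob)
  idx <- cbind(seq_len(nrow(pm)), as.vector(labels) + 1L)
  wv <- w[as.vector(labels) + 1L]
  n <- nrow(pm)
  loss <- -sum(wv * log(pmax(pm[idx], 1e-12))) / n
  onehot <- matrix(0, n, ncol(pm))
  onehot[idx] <- 1
  dscore <- (pm - onehot) * wv / n
  list(loss = loss, dscore = array(dscore, dim(prob)))
}

# Backward pass; returns the gradient of the loss w.r.t. every parameter.
mceunBackward <- function(net, fwd, dscore) {
  cfg <- net$config; P <- net$params; C <- fwd$cache
  d <- dim(C$x)
  gEnc <- lapply(P$enc, zerosLike)
  gDec <- vector("list", cfg$nClasses)
  dEncA <- lapply(C$encA, function(a) array(0, dim(a)))
  dBott <- array(0, dim(C$encA[[cfg$depth]]))
  for (h in seq_len(cfg$nClasses)) {
    hp <- P$dec[[h]]; hc <- C$heads[[h]]
    dOut <- array(dscore[, , h], c(d[1], d[2], 1))
    o <- conv1Bwd(dOut, hc$final, hp$out$W)
    gOut <- list(W = o$dW, b = o$db)
    dcur <- o$dx
    gLev <- list()
    for (l in seq(1, cfg$depth - 1)) {
      lc <- hc$lev[[as.character(l)]]
      lp <- hp$lev[[as.character(l)]]
      dpre <- reluBwd(dcur, lc$pre)
      cv <- convBwd(dpre, list(cols = lc$cols), lc$cat, lp$conv$W)
      cg <- dim(lc$g)[3]
      dg <- cv$dx[, , seq_len(cg), drop = FALSE]
      dagy <- cv$dx[, , cg + seq_len(dim(lc$ag$y)[3]), drop = FALSE]
      ab <- agBwd(dagy, lc$ag, lp$ag, dim(C$encA[[l]]), dim(lc$g))
      dg <- dg + ab$dg
      dEncA[[l]] <- dEncA[[l]] + ab$dx
      gLev[[as.character(l)]] <- list(ag = ab$grads,
                                      conv = list(W = cv$dW, b = cv$db))
      dcur <- upsampleBwd(dg)
    }
    dBott <- dBott + dcur
    gDec[[h]] <- list(lev = gLev, out = gOut)
  }
  if (!is.null(C$dropMask)) dBott <- dBott * C$dropMask
  dEncA[[cfg$depth]] <- dEncA[[cfg$depth]] + dBott
  dcur <- NULL
  for (l in seq(cfg$depth, 1)) {
    da <- dEncA[[l]]
    if (l < cfg$depth)
      da <- da + maxpoolBwd(dcur, C$pools[[l]], dim(C$encA[[l]]))
    dpre <- reluBwd(da, C$encPre[[l]])
    xin <- if (l == 1) C$x else C$pools[[l - 1]]$y
    cv <- convBwd(dpre, list(cols = C$cols[[l]]), xin, P$enc[[l]]$W)
    gEnc[[l]] <- list(W = cv$dW, b = cv$db)
    dcur <- cv$dx
  }
  list(enc = gEnc, dec = gDec)
}

# Default class weights: inverse class frequency, normalized to mean 1.
inverseFrequencyWeights <- function(pairs, nClasses = 6L) {
  counts <- numeric(nClasses)
  for (p in pairs) {
    tb <- tabulate(as.vector(p$labels) + 1L, nClasses)
    counts <- counts + tb
  }
  if (any(counts == 0))
    stop("class absent from all training targets: ",
         paste(names(tissueClasses())[counts == 0], collapse = ", "))
  w <- 1 / counts
  w / mean(w)
}

#' Train a McEUN with weighted cross-entropy and Adam
#'
#' Minimizes the class-weighted cross entropy between predicted and
#' reference segmentations with the Adam optimizer. Five-fold
#' cross-validation monitors overfitting: for each fold a clone of the
#' initialized network is trained on the remaining folds and evaluated on
#' the held-out fold; the returned network is then trained on all pairs.
#' Fully reproducible given `(seed, pairs, config)`.
#'
#' @param net an initialized `"McEUN"` (from [buildMcEUN()])
#' @param pairs list of training samples, each `list(input = [H, W, C]
#'   array, labels = [H, W] integer matrix)`
#' @param classWeights 6-vector of loss weights; default inverse class
#'   frequency normalized to mean 1
#' @param lr Adam learning rate
#' @param epochs training epochs for the final model
#' @param batchSize minibatch size
#' @param seed integer seed controlling shuffling, dropout and folds
#' @param folds number of cross-validation folds (default 5)
#' @param cv run the cross-validation loop? (disable for speed when only the
#'   final model is needed)
#' @param cvEpochs epochs per fold model
#' @return List with elements `net` (trained) and `log` (a `"TrainLog"`:
#'   `data.frame` of per-epoch losses, the fold assignment, and the seed).
#' @export
trainMcEUN <- function(net, pairs, classWeights = NULL, lr = 1e-3,
                       epochs = 20L, batchSize = 4L, seed = 1, folds = 5L,
                       cv = TRUE, cvEpochs = max(3L, epochs %/% 4L)) {
  stopifnot(inherits(net, "McEUN"), length(pairs) >= folds)
  if (is.null(classWeights)) classWeights <- inverseFrequencyWeights(pairs)
  n <- length(pairs)

  evalLoss <- function(params, idx) {
    tmp <- net; tmp$params <- params
    mean(vapply(idx, function(i) {
      f <- mceunForward(tmp, pairs[[i]]$input, train = FALSE)
      mceunLoss(f$prob, pairs[[i]]$labels, classWeights)$loss
    }, numeric(1)))
  }

  trainCore <- function(params, idx, nEpochs) {
    state <- list(t = 0L, m = zerosLike(params), v = zerosLike(params))
    tr <- numeric(nEpochs)
    tmp <- net
    for (ep in seq_len(nEpochs)) {
      ord <- sample(idx)
      epLoss <- 0
      for (start in seq(1, length(ord), by = batchSize)) {
        batch <- ord[start:min(start + batchSize - 1, length(ord))]
        grads <- NULL
        for (i in batch) {
          tmp$params <- params
          f <- mceunForward(tmp, pairs[[i]]$input, train = TRUE)
          lo <- mceunLoss(f$prob, pairs[[i]]$labels, classWeights)
          g <- mceunBackward(tmp, f, lo$dscore)
          epLoss <- epLoss + lo$loss
          grads <- if (is.null(grads)) g else mapParams(`+`, grads, g)
        }
        grads <- mapParams(function(g) g / length(batch), grads)
        st <- adamStep(params, grads, state, lr)
        params <- st$params; state <- st$state
      }
      tr[ep] <- epLoss / length(idx)
    }
    list(params = params, train = tr)
  }

  withSeed(seed, {
    foldOf <- sample(rep(seq_len(folds), length.out = n))
    log <- data.frame()
    if (cv) {
      for (f in seq_len(folds)) {
        res <- trainCore(net$params, which(foldOf != f), cvEpochs)
        vl <- evalLoss(res$params, which(foldOf == f))
        log <- rbind(log, data.frame(phase = "cv", fold = f,
                                     epoch = seq_len(cvEpochs),
                                     trainLoss = res$train,
                                     valLoss = c(rep(NA, cvEpochs - 1), vl)))
      }
    }
    fin <- trainCore(net$params, seq_len(n), epochs)
    log <- rbind(log, data.frame(phase = "final", fold = NA,
                                 epoch = seq_len(epochs),
                                 trainLoss = fin$train, valLoss = NA))
    net$params <- fin$params
    list(net = net,
         log = structure(list(log = log, folds = foldOf, seed = seed),
                         class = "TrainLog"))
  })
}

#' Predict a six-class segmentation with a trained McEUN
#'
#' Applies the network slice-by-slice along the scanner axis to the stacked
#' (scatter-window, photopeak) reconstructions and takes the voxelwise
#' arg-max class over the six heads.
#'
#' @param net a trained `"McEUN"`
#' @param scatterRecon,photopeakRecon volumes normalized to unit mean over
#'   their nonzero support (as produced by
#'   [reconstructInitialEstimates()]); a warning is issued if they do not
#'   look normalized
#' @return Integer label volume (values 0..5).
#' @export
predictSegmentation <- function(net, scatterRecon, photopeakRecon) {
  stopifnot(inherits(net, "McEUN"),
            identical(dim(scatterRecon), dim(photopeakRecon)))
  for (v in list(scatterRecon, photopeakRecon)) {
    m <- mean(v[v > 0])
    if (!is.finite(m) || abs(m - 1) > 0.5)
      warning("input does not look unit-mean normalized (mean ",
              signif(m, 3), ")")
  }
  d <- dim(scatterRecon)
  out <- array(0L, d)
  for (k in seq_len(d[3])) {
    x <- array(c(scatterRecon[, , k], photopeakRecon[, , k]),
               c(d[1], d[2], 2))
    f <- mceunForward(net, x, train = FALSE, keepCache = FALSE)
    out[, , k] <- matrix(max.col(asMat(f$prob), ties.method = "first") - 1L,
                         d[1], d[2])
  }
  out
}

#' Deterministic classical fallback segmentation
#'
#' Training-free six-class segmentation of the transmission-less initial
#' estimates, so the full attenuation-compensation pipeline can run without
#' a trained network: the body is found by thresholding the scatter-window
#' reconstruction (which carries attenuation contrast) and filling
#' interior holes; lungs are low-intensity voxels inside the body; bones
#' are the highest-intensity interior voxels; the skin/adipose rind is the
#' body's outer shell; the table is the high-intensity structure below the
#' body. Deterministic by construction.
#'
#' @param scatterRecon,photopeakRecon unit-mean-normalized volumes on a
#'   common grid
#' @return Integer label volume (values 0..5) consumable by [assignMu()].
#' @export
classicalFallbackSegment <- function(scatterRecon, photopeakRecon) {
  stopifnot(identical(dim(scatterRecon), dim(photopeakRecon)))
  d <- dim(scatterRecon)
  S <- gaussSmooth3d(scatterRecon, 0.8)
  thr <- 0.35 * quantile(S[S > 0], 0.98)
  obj <- S > thr
  outside <- outsideRegion(obj)
  filled <- !outside
  # the component containing the most active (cardiac) voxel is the body
  Psm <- gaussSmooth3d(photopeakRecon, 1.2)
  seedIdx <- arrayInd(which.max(Psm * filled), d)
  seed <- array(FALSE, d); seed[seedIdx] <- TRUE
  body <- floodFill3d(filled, seed)
  if (!any(body)) stop("empty body mask")
  yIdx <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  xIdx <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  bodyCy <- mean(yIdx[body])
  medS <- stats::median(S[body])
  # table: detached structure below the body, or the dim flat slab forming
  # the bottom rows of the filled mask (the blurred couch often bridges the
  # air gap and gets swallowed by the body mask)
  tbl <- filled & !body & yIdx < bodyCy
  occ <- which(apply(filled, 2, any))
  if (length(occ)) {
    cand <- filled & yIdx <= min(occ) + 2 & yIdx < bodyCy
    if (any(cand) && mean(S[cand]) < 0.7 * medS) tbl <- tbl | cand
  }
  body <- body & !tbl
  # flat-field the scatter reconstruction (remove the residual
  # depth-suppression bowl) before intensity rules inside the body
  flat <- S / (gaussSmooth3d(S * body, 5) /
               pmax(gaussSmooth3d(body * 1, 5), 1e-6) + 1e-9)
  # keep intensity rules away from the axial end slices, where the
  # collimator blur leaks out of the field of view and dims everything
  zIdx <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  interior <- erode6(body, 3L, dirs = "xy") & zIdx > 3 & zIdx <= d[3] - 3
  lungs <- interior & flat < 0.85
  lungs <- erode6(dilate6(lungs, 1L, "xy"), 1L, "xy") & interior
  # bones: posterior-central spine by geometric prior plus any strongly
  # hyperintense interior voxels
  cx <- mean(xIdx[body])
  yb <- quantile(yIdx[body], 0.02)
  h <- diff(range(yIdx[body]))
  spineReg <- body & ((xIdx - cx)^2 + (yIdx - (yb + 0.16 * h))^2 <
                      (0.1 * h)^2)
  bones <- (spineReg & flat > 1.0 & !lungs) | (interior & flat > 1.35 &
                                               !lungs)
  rind <- body & !erode6(body, 2L, dirs = "xy")
  lab <- array(0L, d)
  lab[body] <- 2L
  lab[lungs] <- 3L
  lab[bones] <- 4L
  lab[rind & !lungs] <- 1L
  lab[tbl] <- 5L
  lab
}
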