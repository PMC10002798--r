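# Minimal 2-D layer primitives (forward + exact backward) used by the
# multi-decoder attention-gated U-Net. Feature maps are [H, W, C] arrays;
# matrix views are [H*W, C]. All convolutions are "same" with zero padding.

asMat <- function(x) matrix(x, prod(dim(x)[1:2]), dim(x)[3])

im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  xp <- array(0, c(H + 2, W + 2, C))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  cols <- matrix(0, H * W, 9 * C)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    cols[, k * C + seq_len(C)] <-
      matrix(xp[(1:H) + di, (1:W) + dj, , drop = FALSE], H * W, C)
    k <- k + 1L
  }
  cols
}

col2im3 <- function(dcols, H, W, C) {
  xp <- array(0, c(H + 2, W + 2, C))
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    xp[(1:H) + di, (1:W) + dj, ] <- xp[(1:H) + di, (1:W) + dj, , drop = FALSE] +
      array(dcols[, k * C + seq_len(C)], c(H, W, C))
    k <- k + 1L
  }
  xp[2:(H + 1), 2:(W + 1), , drop = FALSE]
}

convFwd <- function(x, W, b) {
  d <- dim(x)
  cols <- im2col3(x)
  y <- cols %*% W
  y <- sweep(y, 2, b, `+`)
  list(y = array(y, c(d[1], d[2], ncol(W))), cols = cols)
}

convBwd <- function(dy, cache, x, W) {
  d <- dim(x)
  dym <- asMat(dy)
  dW <- crossprod(cache$cols, dym)
  db <- colSums(dym)
  dx <- col2im3(dym %*% t(W), d[1], d[2], d[3])
  list(dx = dx, dW = dW, db = db)
}

conv1Fwd <- function(x, W, b) {
  d <- dim(x)
  y <- sweep(asMat(x) %*% W, 2, b, `+`)
  array(y, c(d[1], d[2], ncol(W)))
}

conv1Bwd <- function(dy, x, W) {
  dym <- asMat(dy)
  list(dx = array(dym %*% t(W), dim(x)),
       dW = crossprod(asMat(x), dym), db = colSums(dym))
}

reluFwd <- function(x) pmax(x, 0)
reluBwd <- function(dy, x) dy * (x > 0)

maxpoolFwd <- function(x) {
  d <- dim(x)
  io <- seq(1, d[1], 2); ie <- seq(2, d[1], 2)
  jo <- seq(1, d[2], 2); je <- seq(2, d[2], 2)
  a <- x[io, jo, , drop = FALSE]; b <- x[ie, jo, , drop = FALSE]
  cc <- x[io, je, , drop = FALSE]; dd <- x[ie, je, , drop = FALSE]
  m <- pmax(a, b, cc, dd)
  w1 <- a == m; w2 <- b == m & !w1
  w3 <- cc == m & !w1 & !w2; w4 <- !(w1 | w2 | w3)
  list(y = m, w = list(w1, w2, w3, w4))
}

maxpoolBwd <- function(dy, cache, dimIn) {
  dx <- array(0, dimIn)
  io <- seq(1, dimIn[1], 2); ie <- seq(2, dimIn[1], 2)
  jo <- seq(1, dimIn[2], 2); je <- seq(2, dimIn[2], 2)
  dx[io, jo, ] <- dy * cache$w[[1]]
  dx[ie, jo, ] <- dy * cache$w[[2]]
  dx[io, je, ] <- dy * cache$w[[3]]
  dx[ie, je, ] <- dy * cache$w[[4]]
  dx
}

upsampleFwd <- function(x) {
  d <- dim(x)
  y <- array(0, c(2 * d[1], 2 * d[2], d[3]))
  io <- seq(1, 2 * d[1], 2); ie <- seq(2, 2 * d[1], 2)
  jo <- seq(1, 2 * d[2], 2); je <- seq(2, 2 * d[2], 2)
  y[io, jo, ] <- x; y[ie, jo, ] <- x; y[io, je, ] <- x; y[ie, je, ] <- x
  y
}

upsampleBwd <- function(dy) {
  d <- dim(dy)
  io <- seq(1, d[1], 2); ie <- seq(2, d[1], 2)
  jo <- seq(1, d[2], 2); je <- seq(2, d[2], 2)
  dy[io, jo, , drop = FALSE] + dy[ie, jo, , drop = FALSE] +
    dy[io, je, , drop = FALSE] + dy[ie, je, , drop = FALSE]
}

# Additive attention gate: alpha = sigmoid(psi' relu(Wx x + Wg g + bq)),
# output = x * alpha (gating signal g comes from the coarser level).
agFwd <- function(x, g, p) {
  xm <- asMat(x); gm <- asMat(g)
  qpre <- sweep(xm %*% p$Wx + gm %*% p$Wg, 2, p$bq, `+`)
  q <- pmax(qpre, 0)
  s <- q %*% p$Psi + p$bPsi
  alpha <- 1 / (1 + exp(-s))
  y <- array(xm * as.vector(alpha), dim(x))
  list(y = y, xm = xm, gm = gm, qpre = qpre, q = q, alpha = alpha)
}

agBwd <- function(dy, cache, p, dimX, dimG) {
  dym <- asMat(dy)
  alpha <- as.vector(cache$alpha)
  dalpha <- rowSums(dym * cache$xm)
  dxm <- dym * alpha
  ds <- dalpha * alpha * (1 - alpha)
  dPsi <- crossprod(cache$q, ds)
  dbPsi <- sum(ds)
  dq <- (ds %*% t(p$Psi)) * (cache$qpre > 0)
  dWx <- crossprod(cache$xm, dq)
  dWg <- crossprod(cache$gm, dq)
  dbq <- colSums(dq)
  dxm <- dxm + dq %*% t(p$Wx)
  dgm <- dq %*% t(p$Wg)
  list(dx = array(dxm, dimX), dg = array(dgm, dimG),
       grads = list(Wx = dWx, Wg = dWg, bq = dbq, Psi = dPsi, bPsi = dbPsi))
}

# --- nested parameter-list arithmetic (for Adam) ---------------------------

mapParams <- function(f, ...) {
  ps <- list(...)
  if (is.list(ps[[1]])) {
    nm <- names(ps[[1]])
    keys <- if (is.null(nm)) seq_along(ps[[1]]) else nm  # match by name
    return(stats::setNames(
      lapply(keys,
             function(i) do.call(mapParams, c(list(f), lapply(ps, `[[`, i)))),
      nm))
  }
  do.call(f, ps)
}

zerosLike <- function(p) mapParams(function(x) x * 0, p)

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- mapParams(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- mapParams(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  params <- mapParams(function(p, m, v)
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps), params, state$m, state$v)
  list(params = params, state = state)
}
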