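# Transformer-encoder numerics: parameter initialization, forward pass with
# cache, and the exact reverse-mode gradients. Pre-norm blocks:
#   x <- x + Wo . MHSA(LN1(x));  x <- x + W2 . gelu(W1 . LN2(x))
# followed by a final LayerNorm; the classification-token row is the feature.
# Gradients are verified against finite differences in the test suite.

LN_EPS <- 1e-5

addRow <- function(X, b) X + matrix(b, nrow(X), length(b), byrow = TRUE)

lnForward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  sdv <- sqrt(rowMeans(xc * xc) + LN_EPS)
  xhat <- xc / sdv
  list(y = addRow(sweep(xhat, 2L, g, "*"), b), xhat = xhat, sd = sdv)
}

# dy -> (dx, dg, db); recycling of length-nrow vectors is column-wise, which
# is exactly the per-row broadcast needed here.
lnBackward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxh <- sweep(dy, 2L, g, "*")
  dx <- (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) / cache$sd
  list(dx = dx, dg = dg, db = db)
}

softmaxRows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

gelu <- function(x) x * pnorm(x)
geluGrad <- function(x) pnorm(x) + x * dnorm(x)

#' Split an image into non-overlapping flattened patches
#'
#' Patches are taken in row-major order over the patch grid and each patch is
#' itself flattened row-major, giving the token sequence a transformer
#' encoder consumes.
#'
#' @param image numeric matrix; both dimensions must be divisible by
#'   `patchSize` (resize upstream — there is no silent padding).
#' @param patchSize patch side length.
#' @return matrix with one row per patch, `patchSize^2` columns.
#' @export
patchify <- function(image, patchSize) {
  stopIfNot01Matrix(image)
  ps <- as.integer(patchSize)
  if (nrow(image) %% ps != 0L || ncol(image) %% ps != 0L)
    stop("image dimensions (", nrow(image), "x", ncol(image),
         ") not divisible by patch size ", ps, call. = FALSE)
  gr <- nrow(image) %/% ps; gc <- ncol(image) %/% ps
  out <- matrix(0, gr * gc, ps * ps)
  k <- 0L
  for (r in seq_len(gr)) for (cc in seq_len(gc)) {
    k <- k + 1L
    out[k, ] <- as.vector(t(image[((r - 1L) * ps + 1L):(r * ps),
                                  ((cc - 1L) * ps + 1L):(cc * ps)]))
  }
  out
}

# One encoder's parameters, seeded. Weight matrices use 1/sqrt(fan-in)
# scaling: training starts from scratch on small datasets, where the
# common 0.02 transformer initialization leaves attention logits and token
# features so small that optimization stalls in a near-constant regime.
initEncoder <- function(cfg) {
  D <- cfg@embedDim; ps <- cfg@patchSize
  np <- (cfg@imageSize %/% ps)^2
  M <- as.integer(round(cfg@mlpRatio * D))
  sD <- 1 / sqrt(D)
  withSeed(cfg@seed, {
    blk <- function() list(
      g1 = rep(1, D), b1 = rep(0, D),
      Wqkv = matrix(rnorm(D * 3 * D, 0, sD), D, 3 * D), bqkv = rep(0, 3 * D),
      Wo = matrix(rnorm(D * D, 0, sD), D, D), bo = rep(0, D),
      g2 = rep(1, D), b2 = rep(0, D),
      W1 = matrix(rnorm(D * M, 0, sD), D, M), b1m = rep(0, M),
      W2 = matrix(rnorm(M * D, 0, 1 / sqrt(M)), M, D), b2m = rep(0, D))
    blocks <- lapply(seq_len(cfg@depth), function(i) blk())
    names(blocks) <- paste0("block", seq_len(cfg@depth))
    list(Wp = matrix(rnorm(ps * ps * D, 0, 1 / ps), ps * ps, D),
         bp = rep(0, D),
         cls = matrix(0, 1, D),
         pos = matrix(rnorm((np + 1L) * D, 0, 0.02), np + 1L, D),
         blocks = blocks, gf = rep(1, D), bf = rep(0, D))
  })
}

initHead <- function(inDim, hiddenDim, seed) {
  withSeed(seed, list(
    Wh = matrix(rnorm(inDim * hiddenDim, 0, sqrt(2 / inDim)), inDim, hiddenDim),
    bh = rep(0, hiddenDim),
    Wv = matrix(rnorm(hiddenDim, 0, sqrt(1 / hiddenDim)), hiddenDim, 1),
    bv = 0))
}

# Forward pass over one image's patch matrix X0 (np x ps^2).
# dropMasks: optional list (per block) of list(attn=, mlp=) inverted-dropout
# masks, already scaled by 1/(1-p); NULL disables dropout.
encForward <- function(par, X0, cfg, dropMasks = NULL) {
  D <- cfg@embedDim; H <- cfg@nHeads; dh <- D %/% H
  x <- rbind(par$cls, addRow(X0 %*% par$Wp, par$bp)) + par$pos
  caches <- vector("list", cfg@depth)
  for (l in seq_len(cfg@depth)) {
    b <- par$blocks[[l]]
    c1 <- lnForward(x, b$g1, b$b1)
    QKV <- addRow(c1$y %*% b$Wqkv, b$bqkv)
    Q <- QKV[, 1:D, drop = FALSE]
    K <- QKV[, (D + 1):(2 * D), drop = FALSE]
    V <- QKV[, (2 * D + 1):(3 * D), drop = FALSE]
    A <- vector("list", H)
    O <- matrix(0, nrow(x), D)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Ah <- softmaxRows(Q[, cols, drop = FALSE] %*%
                          t(K[, cols, drop = FALSE]) / sqrt(dh))
      A[[h]] <- Ah
      O[, cols] <- Ah %*% V[, cols, drop = FALSE]
    }
    attn <- addRow(O %*% b$Wo, b$bo)
    if (!is.null(dropMasks)) attn <- attn * dropMasks[[l]]$attn
    x2 <- x + attn
    c2 <- lnForward(x2, b$g2, b$b2)
    hpre <- addRow(c2$y %*% b$W1, b$b1m)
    hg <- gelu(hpre)
    mlp <- addRow(hg %*% b$W2, b$b2m)
    if (!is.null(dropMasks)) mlp <- mlp * dropMasks[[l]]$mlp
    caches[[l]] <- list(xin = x, c1 = c1, Q = Q, K = K, V = V, A = A, O = O,
                        x2 = x2, c2 = c2, hpre = hpre, hg = hg)
    x <- x2 + mlp
  }
  cf <- lnForward(x, par$gf, par$bf)
  list(feat = cf$y[1L, ], xfinal = x, cf = cf, caches = caches, X0 = X0)
}

# Reverse pass. dfeat: gradient w.r.t. the classification-token feature.
# Returns `grads` (a tree with exactly the field order of the parameter
# tree, so optimizer traversals stay aligned) and `dxLastIn`, the gradient
# w.r.t. the token matrix entering the final block (used by
# gradient-weighted class activation mapping).
encBackward <- function(par, fw, dfeat, cfg, dropMasks = NULL) {
  D <- cfg@embedDim; H <- cfg@nHeads; dh <- D %/% H
  Tn <- nrow(fw$xfinal)
  dy <- matrix(0, Tn, D); dy[1L, ] <- dfeat
  lnf <- lnBackward(dy, fw$cf, par$gf)
  dx <- lnf$dx
  gblocks <- vector("list", cfg@depth)
  names(gblocks) <- names(par$blocks)
  dxLastIn <- NULL
  for (l in rev(seq_len(cfg@depth))) {
    b <- par$blocks[[l]]; cc <- fw$caches[[l]]
    dmlp <- if (is.null(dropMasks)) dx else dx * dropMasks[[l]]$mlp
    dW2 <- crossprod(cc$hg, dmlp); db2m <- colSums(dmlp)
    dhg <- dmlp %*% t(b$W2)
    dhpre <- dhg * geluGrad(cc$hpre)
    dW1 <- crossprod(cc$c2$y, dhpre); db1m <- colSums(dhpre)
    dln2y <- dhpre %*% t(b$W1)
    ln2 <- lnBackward(dln2y, cc$c2, b$g2)
    dx2 <- dx + ln2$dx
    dattn <- if (is.null(dropMasks)) dx2 else dx2 * dropMasks[[l]]$attn
    dWo <- crossprod(cc$O, dattn); dbo <- colSums(dattn)
    dO <- dattn %*% t(b$Wo)
    dQ <- matrix(0, Tn, D); dK <- matrix(0, Tn, D); dV <- matrix(0, Tn, D)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Ah <- cc$A[[h]]
      dOh <- dO[, cols, drop = FALSE]
      dA <- dOh %*% t(cc$V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(Ah, dOh)
      dS <- Ah * (dA - rowSums(dA * Ah))
      dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE] / sqrt(dh)
      dK[, cols] <- crossprod(dS, cc$Q[, cols, drop = FALSE]) / sqrt(dh)
    }
    dQKV <- cbind(dQ, dK, dV)
    dWqkv <- crossprod(cc$c1$y, dQKV); dbqkv <- colSums(dQKV)
    dln1y <- dQKV %*% t(b$Wqkv)
    ln1 <- lnBackward(dln1y, cc$c1, b$g1)
    dx <- dx2 + ln1$dx
    if (l == cfg@depth) dxLastIn <- dx
    gblocks[[l]] <- list(g1 = ln1$dg, b1 = ln1$db, Wqkv = dWqkv,
                         bqkv = dbqkv, Wo = dWo, bo = dbo,
                         g2 = ln2$dg, b2 = ln2$db, W1 = dW1, b1m = db1m,
                         W2 = dW2, b2m = db2m)
  }
  dtok <- dx[-1L, , drop = FALSE]
  list(grads = list(Wp = crossprod(fw$X0, dtok), bp = colSums(dtok),
                    cls = dx[1L, , drop = FALSE], pos = dx,
                    blocks = gblocks, gf = lnf$dg, bf = lnf$db),
       dxLastIn = dxLastIn)
}

headForward <- function(hp, f) {
  f <- matrix(f, 1L)
  h <- f %*% hp$Wh + matrix(hp$bh, 1L)
  a <- pmax(h, 0)
  z <- as.numeric(a %*% hp$Wv + hp$bv)
  list(logit = z, f = f, h = h, a = a)
}

headBackward <- function(hp, fw, dlogit) {
  dWv <- t(fw$a) * dlogit
  da <- dlogit * t(hp$Wv)
  dh <- da * (fw$h > 0)
  list(grads = list(Wh = crossprod(fw$f, dh), bh = as.numeric(dh),
                    Wv = dWv, bv = dlogit),
       dfeat = as.numeric(dh %*% t(hp$Wh)))
}

# ---- generic parameter-tree utilities --------------------------------------

zeroLike <- function(p) {
  if (is.list(p)) lapply(p, zeroLike) else p * 0
}

addTrees <- function(a, b) {
  if (is.list(a)) Map(addTrees, a, b) else a + b
}

scaleTree <- function(a, s) {
  if (is.list(a)) lapply(a, scaleTree, s = s) else a * s
}

countLeaves <- function(p) {
  if (is.list(p)) sum(vapply(p, countLeaves, numeric(1))) else length(p)
}

DECAY_LEAVES <- c("Wp", "Wqkv", "Wo", "W1", "W2", "Wh", "Wv")

# One decoupled-weight-decay Adam update. Returns list(p, m, v).
adamStep <- function(p, g, m, v, step, lr, weightDecay,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8, name = "") {
  if (is.list(p)) {
    out <- list(p = p, m = m, v = v)
    for (i in seq_along(p)) {
      nm <- if (is.null(names(p))) "" else names(p)[i]
      r <- adamStep(p[[i]], g[[i]], m[[i]], v[[i]], step, lr, weightDecay,
                    beta1, beta2, eps, nm)
      out$p[[i]] <- r$p; out$m[[i]] <- r$m; out$v[[i]] <- r$v
    }
    return(out)
  }
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g * g
  mh <- m / (1 - beta1^step)
  vh <- v / (1 - beta2^step)
  upd <- mh / (sqrt(vh) + eps)
  if (name %in% DECAY_LEAVES) upd <- upd + weightDecay * p
  list(p = p - lr * upd, m = m, v = v)
}
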