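## Internal training engine: forward/backward passes through
## backbone + fusion + linear softmax classifier, and the Adam update.
## Parameters, gradients and optimizer state share one nested-list
## ("tree") layout so a single recursive map drives the update.

treeMapN <- function(f, trees) {
  if (is.list(trees[[1]])) {
    out <- vector("list", length(trees[[1]]))
    names(out) <- names(trees[[1]])
    for (i in seq_along(trees[[1]]))
      out[[i]] <- treeMapN(f, lapply(trees, `[[`, i))
    out
  } else do.call(f, trees)
}

zeroTree <- function(p) if (is.list(p)) lapply(p, zeroTree) else p * 0

fusionTree <- function(fusion) {
  if (is(fusion, "MetaBlockParams"))
    list(Wf = fusion@Wf, Wg = fusion@Wg, w0f = fusion@w0f, w0g = fusion@w0g)
  else if (is(fusion, "MetaNetParams"))
    list(W1 = fusion@W1, b1 = fusion@b1, W2 = fusion@W2, b2 = fusion@b2)
  else if (is(fusion, "MDNetParams"))
    list(net = fusionTree(fusion@metanet), blk = fusionTree(fusion@metablock),
         Pnet = fusion@Pnet, bnet = fusion@bnet,
         Pblock = fusion@Pblock, bblock = fusion@bblock)
  else list()
}

setFusionTree <- function(fusion, tree) {
  if (is(fusion, "MetaBlockParams")) {
    fusion@Wf <- tree$Wf; fusion@Wg <- tree$Wg
    fusion@w0f <- tree$w0f; fusion@w0g <- tree$w0g
  } else if (is(fusion, "MetaNetParams")) {
    fusion@W1 <- tree$W1; fusion@b1 <- tree$b1
    fusion@W2 <- tree$W2; fusion@b2 <- tree$b2
  } else if (is(fusion, "MDNetParams")) {
    fusion@metanet <- setFusionTree(fusion@metanet, tree$net)
    fusion@metablock <- setFusionTree(fusion@metablock, tree$blk)
    fusion@Pnet <- tree$Pnet; fusion@bnet <- tree$bnet
    fusion@Pblock <- tree$Pblock; fusion@bblock <- tree$bblock
  }
  fusion
}

modelParamTree <- function(model, freezeBackbone = FALSE) {
  tr <- list(fusion = fusionTree(model@fusion),
             W = model@classifier$W, b = model@classifier$b)
  if (!freezeBackbone) tr$backbone <- opParams(model@backbone@ops)
  tr
}

setModelParamTree <- function(model, tree) {
  model@fusion <- setFusionTree(model@fusion, tree$fusion)
  model@classifier$W <- tree$W
  model@classifier$b <- tree$b
  if (!is.null(tree$backbone))
    model@backbone@ops <- setOpParams(model@backbone@ops, tree$backbone)
  model
}

## sum (not mean) over the spatial grid -> N x k
sumPool <- function(arr) {
  d <- dim(arr)
  t(matrix(colSums(matrix(arr, nrow = d[1] * d[2])), nrow = d[3]))
}

## gradient of global average pooling: N x k -> h x w x k x N
unpoolGrad <- function(g, h, w) {
  out <- spatialBroadcast(t(g), h, w) / (h * w)
  dim(out) <- c(h, w, ncol(g), nrow(g))
  out
}

fusionForwardT <- function(fusion, fmap, M) {
  d <- dim(fmap)
  if (is(fusion, "NoneFusion"))
    return(list(F = globalAvgPool(fmap)))
  if (is(fusion, "ConcatFusion"))
    return(list(F = cbind(globalAvgPool(fmap), M)))
  if (is(fusion, "MetaNetParams")) {
    a1 <- M %*% fusion@W1 + rep(fusion@b1, each = nrow(M))
    r <- pmax(a1, 0)
    s <- sigmoid(r %*% fusion@W2 + rep(fusion@b2, each = nrow(M)))
    sb <- spatialBroadcast(t(s), d[1], d[2])
    y <- fmap * sb
    return(list(F = globalAvgPool(y), a1 = a1, r = r, s = s, sb = sb))
  }
  if (is(fusion, "MetaBlockParams")) {
    f <- M %*% fusion@Wf + rep(fusion@w0f, each = nrow(M))
    g <- M %*% fusion@Wg + rep(fusion@w0g, each = nrow(M))
    fb <- spatialBroadcast(t(f), d[1], d[2])
    tg <- tanh(fmap * fb)
    y <- sigmoid(tg + spatialBroadcast(t(g), d[1], d[2]))
    return(list(F = globalAvgPool(y), fb = fb, tg = tg, y = y))
  }
  if (is(fusion, "MDNetParams")) {
    cnet <- fusionForwardT(fusion@metanet, fmap, M)
    cblk <- fusionForwardT(fusion@metablock, fmap, M)
    znet <- cnet$F %*% fusion@Pnet + rep(fusion@bnet, each = nrow(M))
    zblk <- cblk$F %*% fusion@Pblock + rep(fusion@bblock, each = nrow(M))
    return(list(F = cbind(znet, zblk), cnet = cnet, cblk = cblk))
  }
  stop("unknown fusion class")
}

## returns list(grads = <fusion grad tree>, gmap = grad w.r.t. feature map)
fusionBackwardT <- function(fusion, cache, fmap, M, gF) {
  d <- dim(fmap)
  if (is(fusion, "NoneFusion"))
    return(list(grads = list(), gmap = unpoolGrad(gF, d[1], d[2])))
  if (is(fusion, "ConcatFusion"))
    return(list(grads = list(),
                gmap = unpoolGrad(gF[, seq_len(d[3]), drop = FALSE], d[1], d[2])))
  if (is(fusion, "MetaNetParams")) {
    gy <- unpoolGrad(gF, d[1], d[2])
    gs <- sumPool(gy * fmap)
    gmap <- gy * cache$sb
    ga2 <- gs * cache$s * (1 - cache$s)
    gW2 <- t(cache$r) %*% ga2
    gb2 <- colSums(ga2)
    gr <- ga2 %*% t(fusion@W2)
    ga1 <- gr * (cache$a1 > 0)
    return(list(grads = list(W1 = t(M) %*% ga1, b1 = colSums(ga1),
                             W2 = gW2, b2 = gb2),
                gmap = gmap))
  }
  if (is(fusion, "MetaBlockParams")) {
    gy <- unpoolGrad(gF, d[1], d[2])
    gv <- gy * cache$y * (1 - cache$y)
    gg <- sumPool(gv)
    gu <- gv * (1 - cache$tg^2)
    gmap <- gu * cache$fb
    gf <- sumPool(gu * fmap)
    return(list(grads = list(Wf = t(M) %*% gf, Wg = t(M) %*% gg,
                             w0f = colSums(gf), w0g = colSums(gg)),
                gmap = gmap))
  }
  if (is(fusion, "MDNetParams")) {
    dF <- fusion@dFuse
    gznet <- gF[, seq_len(dF), drop = FALSE]
    gzblk <- gF[, dF + seq_len(dF), drop = FALSE]
    bnet <- fusionBackwardT(fusion@metanet, cache$cnet, fmap, M,
                            gznet %*% t(fusion@Pnet))
    bblk <- fusionBackwardT(fusion@metablock, cache$cblk, fmap, M,
                            gzblk %*% t(fusion@Pblock))
    return(list(grads = list(net = bnet$grads, blk = bblk$grads,
                             Pnet = t(cache$cnet$F) %*% gznet,
                             bnet = colSums(gznet),
                             Pblock = t(cache$cblk$F) %*% gzblk,
                             bblock = colSums(gzblk)),
                gmap = bnet$gmap + bblk$gmap))
  }
  stop("unknown fusion class")
}

## full forward; when train = TRUE a dropout mask is drawn from the RNG
modelForward <- function(model, images, M, train = FALSE, cache = FALSE) {
  bb <- backboneForward(model@backbone@ops, images, cache = cache)
  fus <- fusionForwardT(model@fusion, bb$out, M)
  Fv <- fus$F
  mask <- NULL
  if (train && model@dropout > 0) {
    mask <- matrix(stats::rbinom(length(Fv), 1L, 1 - model@dropout) /
                     (1 - model@dropout), nrow(Fv), ncol(Fv))
    Fv <- Fv * mask
  }
  logits <- Fv %*% model@classifier$W +
    rep(model@classifier$b, each = nrow(Fv))
  list(logits = logits, Fdrop = Fv, mask = mask,
       fmap = bb$out, bbCache = bb$caches, fusCache = fus)
}

softmaxProbs <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## cross-entropy loss and gradient w.r.t. logits; y is an integer class
## index vector, wts per-sample weights summing over the batch use
crossEntropy <- function(logits, y, wts = NULL) {
  P <- softmaxProbs(logits)
  n <- nrow(P)
  if (is.null(wts)) wts <- rep(1, n)
  py <- P[cbind(seq_len(n), y)]
  loss <- -sum(wts * log(pmax(py, 1e-12))) / sum(wts)
  G <- P
  G[cbind(seq_len(n), y)] <- G[cbind(seq_len(n), y)] - 1
  G <- G * (wts / sum(wts))
  list(loss = loss, glogits = G, probs = P)
}

modelBackward <- function(model, fwd, M, glogits, freezeBackbone = FALSE) {
  gW <- t(fwd$Fdrop) %*% glogits
  gb <- colSums(glogits)
  gF <- glogits %*% t(model@classifier$W)
  if (!is.null(fwd$mask)) gF <- gF * fwd$mask
  fb <- fusionBackwardT(model@fusion, fwd$fusCache, fwd$fmap, M, gF)
  tr <- list(fusion = fb$grads, W = gW, b = gb)
  if (!freezeBackbone) {
    bbw <- backboneBackward(model@backbone@ops, fwd$bbCache, fb$gmap)
    tr$backbone <- bbw$grads
  }
  tr
}

adamInit <- function(paramTree)
  list(m = zeroTree(paramTree), v = zeroTree(paramTree), t = 0L)

adamStep <- function(paramTree, gradTree, state, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- treeMapN(function(m, g) beta1 * m + (1 - beta1) * g,
                      list(state$m, gradTree))
  state$v <- treeMapN(function(v, g) beta2 * v + (1 - beta2) * g * g,
                      list(state$v, gradTree))
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  paramTree <- treeMapN(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                        list(paramTree, state$m, state$v))
  list(params = paramTree, state = state)
}
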