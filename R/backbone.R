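## Convolutional feature extractors.  A backbone is an ordered list of
## ops (conv / average pool / dense block) run on H x W x 3 x N image
## arrays; fusion blocks attach to the final pre-pooling feature map.

reluFw <- function(x) { x[x < 0] <- 0; x }

## 2x2 (or k x k) non-overlapping average pooling
avgPoolFw <- function(x, k) {
  d <- dim(x)
  Ho <- d[1] %/% k; Wo <- d[2] %/% k
  if (Ho < 1L || Wo < 1L) stop("average pool would empty the spatial grid")
  x <- x[seq_len(Ho * k), seq_len(Wo * k), , , drop = FALSE]
  a <- colSums(array(x, c(k, Ho * Wo * k * d[3] * d[4])))          # pool rows
  dim(a) <- c(Ho, Wo * k, d[3], d[4])
  a <- aperm(a, c(2, 1, 3, 4))
  a <- colSums(array(a, c(k, Wo * Ho * d[3] * d[4])))              # pool cols
  dim(a) <- c(Wo, Ho, d[3], d[4])
  aperm(a, c(2, 1, 3, 4)) / (k * k)
}

avgPoolBw <- function(gy, k, inDim) {
  d <- dim(gy)
  gx <- array(0, inDim)
  gx[seq_len(d[1] * k), seq_len(d[2] * k), , ] <-
    gy[rep(seq_len(d[1]), each = k), rep(seq_len(d[2]), each = k), , ,
       drop = FALSE] / (k * k)
  gx
}

convInit <- function(kh, kw, cin, cout) {
  fan <- kh * kw * cin
  list(w = array(uniformInit(kh * kw * cin * cout, fan), c(kh, kw, cin, cout)),
       b = numeric(cout))
}

#' Create dense-block parameters
#'
#' @param inChannels channel count of the block input.
#' @param growth channels each layer adds.
#' @param L number of layers (0 gives the identity block).
#' @param kernel spatial kernel size of each layer's convolution
#'   (odd; same-padded).
#' @param seed optional seed for the uniform initialization.
#' @return a [DenseBlockParams-class].
#' @export
denseBlockParams <- function(inChannels, growth, L, kernel = 3L, seed = NULL) {
  inChannels <- as.integer(inChannels); growth <- as.integer(growth)
  withSeed(seed, new("DenseBlockParams",
    inChannels = inChannels, growth = growth,
    layers = lapply(seq_len(L), function(l)
      convInit(kernel, kernel, inChannels + (l - 1L) * growth, growth))))
}

## channel-concatenate two H x W x C x N arrays
ccat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (!all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
    stop("cannot concatenate feature maps with mismatched spatial or batch dimensions")
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' Densely connected block forward pass
#'
#' Layer `l` consumes the channel-concatenation of the block input and
#' the outputs of all preceding layers, and emits `growth` new channels
#' (same-padded convolution + ReLU); the block output concatenates the
#' input with every layer's output, so it carries
#' `inChannels + L * growth` channels at the input's spatial size.
#' With `L = 0` the block is the identity.
#'
#' @param x0 feature map `h x w x inChannels (x N)`.
#' @param params a [denseBlockParams()] object.
#' @return feature map with `inChannels + L * growth` channels.
#' @export
denseBlockForward <- function(x0, params) {
  stopifnot(is(params, "DenseBlockParams"))
  x <- asFeatureMap(x0)
  if (dim(x)[3] != params@inChannels)
    stop(sprintf("dense block expects %d input channels, got %d",
                 params@inChannels, dim(x)[3]))
  for (layer in params@layers) {
    y <- reluFw(conv2d_fw(x, layer$w, layer$b, 1L, (dim(layer$w)[1] - 1L) %/% 2L))
    x <- ccat(x, y)
  }
  if (length(dim(x0)) == 3L) dim(x) <- dim(x)[1:3]
  x
}

## ---- backbone op-list forward / backward -------------------------------

backboneForward <- function(ops, x, cache = FALSE) {
  caches <- if (cache) vector("list", length(ops)) else NULL
  for (i in seq_along(ops)) {
    op <- ops[[i]]
    if (op$type == "conv") {
      xin <- x
      x <- conv2d_fw(x, op$w, op$b, op$stride, op$pad)
      if (op$act == "relu") x <- reluFw(x)
      if (cache) caches[[i]] <- list(x = xin, y = x)
    } else if (op$type == "avgpool") {
      if (cache) caches[[i]] <- list(inDim = dim(x))
      x <- avgPoolFw(x, op$k)
    } else if (op$type == "dense") {
      ins <- if (cache) vector("list", length(op$layers)) else NULL
      outs <- if (cache) vector("list", length(op$layers)) else NULL
      for (l in seq_along(op$layers)) {
        ly <- op$layers[[l]]
        pad <- (dim(ly$w)[1] - 1L) %/% 2L
        if (cache) ins[[l]] <- x
        y <- reluFw(conv2d_fw(x, ly$w, ly$b, 1L, pad))
        if (cache) outs[[l]] <- y
        x <- ccat(x, y)
      }
      if (cache) caches[[i]] <- list(ins = ins, outs = outs)
    } else stop("unknown backbone op: ", op$type)
  }
  list(out = x, caches = caches)
}

backboneBackward <- function(ops, caches, gy) {
  grads <- vector("list", length(ops))
  g <- gy
  for (i in rev(seq_along(ops))) {
    op <- ops[[i]]; cc <- caches[[i]]
    if (op$type == "conv") {
      if (op$act == "relu") g <- g * (cc$y > 0)
      bw <- conv2d_bw(cc$x, op$w, g, op$stride, op$pad)
      grads[[i]] <- list(w = bw$gw, b = bw$gb)
      g <- bw$gx
    } else if (op$type == "avgpool") {
      grads[[i]] <- list()
      g <- avgPoolBw(g, op$k, cc$inDim)
    } else if (op$type == "dense") {
      lg <- vector("list", length(op$layers))
      for (l in rev(seq_along(op$layers))) {
        ly <- op$layers[[l]]
        pad <- (dim(ly$w)[1] - 1L) %/% 2L
        cprev <- dim(cc$ins[[l]])[3]
        gprev <- g[, , seq_len(cprev), , drop = FALSE]
        gout <- g[, , cprev + seq_len(dim(g)[3] - cprev), , drop = FALSE]
        gout <- gout * (cc$outs[[l]] > 0)
        bw <- conv2d_bw(cc$ins[[l]], ly$w, gout, 1L, pad)
        lg[[l]] <- list(w = bw$gw, b = bw$gb)
        g <- gprev + bw$gx
      }
      grads[[i]] <- lg
    }
  }
  list(gx = g, grads = grads)
}

## ---- concrete backbones ------------------------------------------------

#' Tiny densely connected test backbone
#'
#' A desk-scale feature extractor for testing and synthetic
#' experiments: a stride-2 stem convolution, a 2x2 average pool and a
#' two-layer dense block, mapping `32 x 32 x 3` images to an
#' `8 x 8 x kImg` feature map.  `kImg` must be divisible by 4 (half the
#' channels come from the stem, half from the dense block).
#'
#' @param kImg output channel count (default 16).
#' @param seed seed for the uniform weight initialization.
#' @return a [DenseBackbone-class].
#' @export
tinyDenseBackbone <- function(kImg = 16L, seed = 1L) {
  kImg <- as.integer(kImg)
  if (kImg < 4L || kImg %% 4L != 0L)
    stop("tiny-dense-test requires kImg divisible by 4")
  stemC <- kImg %/% 2L
  growth <- kImg %/% 4L
  withSeed(seed, {
    stem <- convInit(3L, 3L, 3L, stemC)
    blk <- denseBlockParams(stemC, growth, 2L)
    new("DenseBackbone", name = "tiny-dense-test", kImg = kImg,
        ops = list(
          c(list(type = "conv", stride = 2L, pad = 1L, act = "relu"), stem),
          list(type = "avgpool", k = 2L),
          list(type = "dense", layers = blk@layers)))
  })
}

buildDenseNet169 <- function(seed = 1L) {
  withSeed(seed, {
    ops <- list(c(list(type = "conv", stride = 2L, pad = 3L, act = "relu"),
                  convInit(7L, 7L, 3L, 64L)),
                list(type = "avgpool", k = 2L))
    ch <- 64L
    stages <- c(6L, 12L, 32L, 32L)
    for (s in seq_along(stages)) {
      blk <- denseBlockParams(ch, 32L, stages[s])
      ops <- c(ops, list(list(type = "dense", layers = blk@layers)))
      ch <- ch + 32L * stages[s]
      if (s < length(stages)) {           # 0.5 compression transition
        half <- ch %/% 2L
        ops <- c(ops, list(c(list(type = "conv", stride = 1L, pad = 0L,
                                  act = "relu"), convInit(1L, 1L, ch, half)),
                           list(type = "avgpool", k = 2L)))
        ch <- half
      }
    }
    new("DenseBackbone", name = "densenet169", kImg = ch, ops = ops)
  })
}

#' Instantiate a named backbone, optionally loading stored weights
#'
#' Supported names:
#' * `"tiny-dense-test"` — the desk-scale reference block of
#'   [tinyDenseBackbone()] (`kImg` configurable via `...`).
#' * `"densenet169"` — a structural adapter with the 169-layer dense
#'   architecture's channel bookkeeping (stem 64, blocks 6/12/32/32,
#'   growth 32, 0.5-compression transitions, `kImg = 1664`), using
#'   plain ReLU convolutions.  It serves the weight-loading contract;
#'   it is not a trained ImageNet model.
#'
#' Without `weightsPath` the backbone is randomly initialized from the
#' given seed; with it, weights previously stored by
#' [saveBackboneWeights()] are restored and checked against the
#' architecture.
#'
#' @param name backbone identifier.
#' @param weightsPath optional path to a stored weight file.
#' @param seed seed for random initialization.
#' @param ... passed to the named constructor (e.g. `kImg` for the tiny
#'   backbone).
#' @return a [DenseBackbone-class].
#' @export
loadPretrained <- function(name, weightsPath = NULL, seed = 1L, ...) {
  supported <- c("tiny-dense-test", "densenet169")
  if (!name %in% supported)
    stop("unknown backbone '", name, "'; supported: ",
         paste(supported, collapse = ", "))
  bb <- switch(name,
               "tiny-dense-test" = tinyDenseBackbone(seed = seed, ...),
               "densenet169" = buildDenseNet169(seed = seed))
  if (!is.null(weightsPath)) {
    stored <- readRDS(weightsPath)
    if (!identical(stored$name, name))
      stop(sprintf("weight file was saved for backbone '%s', not '%s'",
                   stored$name, name))
    bb@ops <- tryCatch(setOpParams(bb@ops, stored$params),
                       error = function(e)
                         stop("weight/architecture mismatch: ",
                              conditionMessage(e), call. = FALSE))
  }
  bb
}

#' Persist backbone weights
#'
#' @param backbone a [DenseBackbone-class].
#' @param path file path for the weight file.
#' @return `path`, invisibly.
#' @export
saveBackboneWeights <- function(backbone, path) {
  saveRDS(list(name = backbone@name, kImg = backbone@kImg,
               params = opParams(backbone@ops)), path)
  invisible(path)
}

## extract / restore the trainable parameters of an op list
opParams <- function(ops) lapply(ops, function(op) {
  if (op$type == "conv") list(w = op$w, b = op$b)
  else if (op$type == "dense") lapply(op$layers, function(l) list(w = l$w, b = l$b))
  else list()
})

setOpParams <- function(ops, params) {
  if (length(ops) != length(params)) stop("op count differs")
  for (i in seq_along(ops)) {
    op <- ops[[i]]; p <- params[[i]]
    if (op$type == "conv") {
      if (!identical(dim(op$w), dim(p$w))) stop("conv weight shape differs")
      ops[[i]]$w <- p$w; ops[[i]]$b <- p$b
    } else if (op$type == "dense") {
      if (length(op$layers) != length(p)) stop("dense layer count differs")
      for (l in seq_along(op$layers)) {
        if (!identical(dim(op$layers[[l]]$w), dim(p[[l]]$w)))
          stop("dense layer weight shape differs")
        ops[[i]]$layers[[l]]$w <- p[[l]]$w
        ops[[i]]$layers[[l]]$b <- p[[l]]$b
      }
    }
  }
  ops
}

#' @describeIn kImg declared output channel count of a backbone.
#' @export
setMethod("kImg", "DenseBackbone", function(x) x@kImg)

#' @describeIn extractFeatures run the op list on an image batch.
#' @export
setMethod("extractFeatures", "DenseBackbone", function(backbone, images) {
  x <- asFeatureMap(images)
  out <- backboneForward(backbone@ops, x)$out
  if (dim(out)[3] != backbone@kImg)
    stop("backbone produced a channel count different from its declaration")
  out
})

setMethod("show", "DenseBackbone", function(object)
  cat(sprintf("DenseBackbone '%s': %d ops, kImg = %d\n",
              object@name, length(object@ops), object@kImg)))
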