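## Fusion blocks: MetaBlock (tanh/sigmoid gated modulation), MetaNet
## (multiplicative channel reweighting), MD-Net (pooled + projected
## combination of both), plus the Concatenation and None baselines.
##
## Feature maps are arrays h x w x k x N (a single sample may omit the
## batch dimension); encoded metadata is a vector of length dMeta or an
## N x dMeta matrix.

## evaluate expr under a temporary seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

uniformInit <- function(n, fanIn) {
  a <- 1 / sqrt(max(fanIn, 1))
  stats::runif(n, -a, a)
}

asFeatureMap <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("feature map must be an h x w x k (x N) array")
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  if (!all(is.finite(x))) stop("feature map contains non-finite entries")
  x
}

asMetaMatrix <- function(xMeta, n = NULL) {
  if (is.null(dim(xMeta))) xMeta <- matrix(xMeta, nrow = 1L)
  if (!is.null(n) && nrow(xMeta) != n)
    stop(sprintf("metadata batch (%d) does not match image batch (%d)",
                 nrow(xMeta), n))
  xMeta
}

sigmoid <- function(z) 1 / (1 + exp(-z))

## broadcast a k x N matrix of per-channel, per-sample scalars over an
## h x w spatial grid (returns a vector conformable with an h,w,k,N array)
spatialBroadcast <- function(v, h, w) rep(v, each = h * w)

#' Create MetaBlock parameters
#'
#' The MetaBlock modulates an image feature map with two affine
#' functions of the metadata vector: `f_b(x) = Wf' x + w0f` scales each
#' channel inside a tanh gate and `g_b(x) = Wg' x + w0g` shifts it
#' inside a sigmoid gate (see [metaBlockForward()]).
#'
#' @param dMeta encoded metadata dimension.
#' @param kImg image feature channel count.
#' @param seed optional integer; when given, initialization is drawn
#'   from a seeded uniform scheme (±1/sqrt(dMeta)) without disturbing
#'   the caller's RNG state.
#' @param zero logical; all-zero initialization (useful for tests).
#' @return a [MetaBlockParams-class][FusionParams-class].
#' @export
metaBlockParams <- function(dMeta, kImg, seed = NULL, zero = FALSE) {
  dMeta <- as.integer(dMeta); kImg <- as.integer(kImg)
  if (zero)
    return(new("MetaBlockParams",
               Wf = matrix(0, dMeta, kImg), Wg = matrix(0, dMeta, kImg),
               w0f = numeric(kImg), w0g = numeric(kImg)))
  withSeed(seed, new("MetaBlockParams",
    Wf = matrix(uniformInit(dMeta * kImg, dMeta), dMeta, kImg),
    Wg = matrix(uniformInit(dMeta * kImg, dMeta), dMeta, kImg),
    w0f = uniformInit(kImg, dMeta), w0g = uniformInit(kImg, dMeta)))
}

#' Create MetaNet parameters
#'
#' A two-layer subnetwork (affine, ReLU, affine, sigmoid) mapping the
#' metadata vector to one multiplicative scale per image channel; the
#' affine maps are equivalent to the kernel-size-1 one-dimensional
#' convolutions of the original formulation applied to a length-1
#' sequence.
#'
#' @inheritParams metaBlockParams
#' @param hidden width of the intermediate layer; defaults to `dMeta`.
#' @return a [MetaNetParams-class][FusionParams-class].
#' @export
metaNetParams <- function(dMeta, kImg, hidden = dMeta, seed = NULL,
                          zero = FALSE) {
  dMeta <- as.integer(dMeta); kImg <- as.integer(kImg)
  hidden <- as.integer(hidden)
  if (zero)
    return(new("MetaNetParams",
               W1 = matrix(0, dMeta, hidden), b1 = numeric(hidden),
               W2 = matrix(0, hidden, kImg), b2 = numeric(kImg)))
  withSeed(seed, new("MetaNetParams",
    W1 = matrix(uniformInit(dMeta * hidden, dMeta), dMeta, hidden),
    b1 = uniformInit(hidden, dMeta),
    W2 = matrix(uniformInit(hidden * kImg, hidden), hidden, kImg),
    b2 = uniformInit(kImg, hidden)))
}

#' Create MD-Net parameters
#'
#' Wraps a [metaNetParams()] and a [metaBlockParams()] block plus the
#' two affine projections that bring each block's pooled output to the
#' common fused dimension `dFuse` before concatenation.
#'
#' @inheritParams metaNetParams
#' @param dFuse common projected dimension; defaults to `ceiling(kImg/2)`
#'   so the fused vector (length `2*dFuse`) stays close to `kImg`.
#' @return an [MDNetParams-class][FusionParams-class].
#' @export
mdnetParams <- function(dMeta, kImg, dFuse = ceiling(kImg / 2),
                        hidden = dMeta, seed = NULL, zero = FALSE) {
  dMeta <- as.integer(dMeta); kImg <- as.integer(kImg)
  dFuse <- as.integer(dFuse)
  mk <- function() new("MDNetParams",
    metanet = metaNetParams(dMeta, kImg, hidden, zero = zero),
    metablock = metaBlockParams(dMeta, kImg, zero = zero),
    Pnet = if (zero) matrix(0, kImg, dFuse) else
      matrix(uniformInit(kImg * dFuse, kImg), kImg, dFuse),
    bnet = if (zero) numeric(dFuse) else uniformInit(dFuse, kImg),
    Pblock = if (zero) matrix(0, kImg, dFuse) else
      matrix(uniformInit(kImg * dFuse, kImg), kImg, dFuse),
    bblock = if (zero) numeric(dFuse) else uniformInit(dFuse, kImg),
    dFuse = dFuse)
  withSeed(seed, mk())
}

#' @rdname fuseFeatures
#' @export
concatFusion <- function() new("ConcatFusion")

#' @rdname fuseFeatures
#' @export
noneFusion <- function() new("NoneFusion")

#' Metadata-to-channel affine modifiers of the MetaBlock
#'
#' `gateScale` computes `f_b(x_meta) = Wf' x_meta + w0f`, the
#' per-channel multiplicative modifier applied inside the tanh gate;
#' `gateShift` computes `g_b(x_meta) = Wg' x_meta + w0g`, the additive
#' modifier applied inside the sigmoid gate.
#'
#' @param xMeta numeric vector of length `dMeta` or `N x dMeta` matrix.
#' @param params a [MetaBlockParams-class][FusionParams-class].
#' @return numeric vector of length `kImg` (vector input) or `N x kImg`
#'   matrix.
#' @export
gateScale <- function(xMeta, params) {
  stopifnot(is(params, "MetaBlockParams"))
  single <- is.null(dim(xMeta))
  M <- asMetaMatrix(xMeta)
  if (ncol(M) != nrow(params@Wf))
    stop(sprintf("metadata length %d does not match d_meta %d",
                 ncol(M), nrow(params@Wf)))
  out <- M %*% params@Wf + rep(params@w0f, each = nrow(M))
  if (single) drop(out) else out
}

#' @rdname gateScale
#' @export
gateShift <- function(xMeta, params) {
  stopifnot(is(params, "MetaBlockParams"))
  single <- is.null(dim(xMeta))
  M <- asMetaMatrix(xMeta)
  if (ncol(M) != nrow(params@Wg))
    stop(sprintf("metadata length %d does not match d_meta %d",
                 ncol(M), nrow(params@Wg)))
  out <- M %*% params@Wg + rep(params@w0g, each = nrow(M))
  if (single) drop(out) else out
}

checkModifier <- function(fmod, k, n) {
  if (is.null(dim(fmod))) fmod <- matrix(fmod, nrow = n, ncol = length(fmod),
                                         byrow = TRUE)
  if (ncol(fmod) != k)
    stop(sprintf("modifier has %d channels, feature map has %d",
                 ncol(fmod), k))
  if (nrow(fmod) != n)
    stop("modifier batch does not match feature-map batch")
  fmod
}

#' Hyperbolic-tangent gate of the MetaBlock
#'
#' Scales every channel of the feature map by its metadata-derived
#' modifier (broadcast over the spatial grid) and squashes through
#' `tanh`, confining every feature value to (-1, 1).
#'
#' @param xImg feature map `h x w x k (x N)`.
#' @param fmod per-channel modifier: length-`k` vector (shared across
#'   the batch) or `N x k` matrix.
#' @return gated feature map, same shape as `xImg`.
#' @export
tanhGate <- function(xImg, fmod) {
  x <- asFeatureMap(xImg)
  d <- dim(x)
  fmod <- checkModifier(fmod, d[3], d[4])
  out <- tanh(x * spatialBroadcast(t(fmod), d[1], d[2]))
  dim(out) <- dim(xImg)
  out
}

#' Sigmoid gate of the MetaBlock
#'
#' Adds the metadata-derived per-channel shift to the tanh-gated map
#' (broadcast spatially) and squashes through the logistic function,
#' confining every feature value to (0, 1).
#'
#' @param tGate feature map emitted by [tanhGate()].
#' @param gmod per-channel shift: length-`k` vector or `N x k` matrix.
#' @return gated feature map, same shape as `tGate`.
#' @export
sigmoidGate <- function(tGate, gmod) {
  x <- asFeatureMap(tGate)
  d <- dim(x)
  gmod <- checkModifier(gmod, d[3], d[4])
  out <- sigmoid(x + spatialBroadcast(t(gmod), d[1], d[2]))
  dim(out) <- dim(tGate)
  out
}

#' MetaBlock forward pass: metadata-gated feature modulation
#'
#' Computes `sigma(tanh(f_b(x_meta) * x_img) + g_b(x_meta))` with the
#' per-channel modifiers of [gateScale()] and [gateShift()] broadcast
#' over the spatial grid.  The output has exactly the shape of the
#' input feature map, with every value in (0, 1).
#'
#' @param xImg feature map `h x w x k (x N)`.
#' @param xMeta encoded metadata vector or `N x dMeta` matrix.
#' @param params a [metaBlockParams()] object.
#' @return modulated feature map, same shape as `xImg`.
#' @export
metaBlockForward <- function(xImg, xMeta, params) {
  x <- asFeatureMap(xImg)
  M <- asMetaMatrix(xMeta, dim(x)[4])
  f <- gateScale(M, params)
  g <- gateShift(M, params)
  out <- sigmoidGate(tanhGate(x, f), g)
  dim(out) <- dim(xImg)
  out
}

#' Per-channel scales of the MetaNet subnetwork
#'
#' `sigma(W2' relu(W1' x_meta + b1) + b2)`, one value in (0, 1) per
#' image channel.
#'
#' @inheritParams gateScale
#' @param params a [metaNetParams()] object.
#' @return length-`kImg` vector or `N x kImg` matrix of channel scales.
#' @export
metaNetScales <- function(xMeta, params) {
  stopifnot(is(params, "MetaNetParams"))
  single <- is.null(dim(xMeta))
  M <- asMetaMatrix(xMeta)
  if (ncol(M) != nrow(params@W1))
    stop(sprintf("metadata length %d does not match d_meta %d",
                 ncol(M), nrow(params@W1)))
  h <- pmax(M %*% params@W1 + rep(params@b1, each = nrow(M)), 0)
  s <- sigmoid(h %*% params@W2 + rep(params@b2, each = nrow(M)))
  if (single) drop(s) else s
}

#' MetaNet forward pass: multiplicative channel reweighting
#'
#' The metadata vector is mapped through a two-layer subnetwork to one
#' scale in (0, 1) per feature channel; each channel of the image
#' feature map is multiplied by its scale (broadcast spatially), so the
#' metadata directly controls the importance of each channel.  Output
#' magnitudes never exceed the input's and signs are preserved.
#'
#' @inheritParams metaBlockForward
#' @param params a [metaNetParams()] object.
#' @return reweighted feature map, same shape as `xImg`.
#' @export
metaNetForward <- function(xImg, xMeta, params) {
  x <- asFeatureMap(xImg)
  d <- dim(x)
  M <- asMetaMatrix(xMeta, d[4])
  s <- metaNetScales(M, params)
  out <- x * spatialBroadcast(t(s), d[1], d[2])
  dim(out) <- dim(xImg)
  out
}

#' Global average pooling
#'
#' Collapses the spatial grid of a feature map to one value per
#' channel.
#'
#' @param xImg feature map `h x w x k (x N)`.
#' @return `N x k` matrix of channel means.
#' @export
globalAvgPool <- function(xImg) {
  x <- asFeatureMap(xImg)
  d <- dim(x)
  t(matrix(colMeans(matrix(x, nrow = d[1] * d[2])), nrow = d[3]))
}

#' MD-Net fusion of the MetaNet and MetaBlock streams
#'
#' Runs both blocks on the same feature map, globally average-pools
#' each output to a `kImg` vector, projects each through its own affine
#' map to the common dimension `dFuse`, and concatenates the two
#' projections (the two streams are kept unmixed for the classifier).
#'
#' @inheritParams metaBlockForward
#' @param params an [mdnetParams()] object.
#' @return `N x (2*dFuse)` matrix of fused feature vectors.
#' @export
mdnetFuse <- function(xImg, xMeta, params) {
  stopifnot(is(params, "MDNetParams"))
  x <- asFeatureMap(xImg)
  M <- asMetaMatrix(xMeta, dim(x)[4])
  pnet <- globalAvgPool(metaNetForward(x, M, params@metanet))
  pblk <- globalAvgPool(metaBlockForward(x, M, params@metablock))
  znet <- pnet %*% params@Pnet + rep(params@bnet, each = nrow(pnet))
  zblk <- pblk %*% params@Pblock + rep(params@bblock, each = nrow(pblk))
  cbind(znet, zblk)
}

#' Concatenation baseline
#'
#' Globally average-pooled image features concatenated with the raw
#' encoded metadata vector.
#'
#' @inheritParams metaBlockForward
#' @return `N x (kImg + dMeta)` matrix.
#' @export
concatFuse <- function(xImg, xMeta) {
  x <- asFeatureMap(xImg)
  M <- asMetaMatrix(xMeta, dim(x)[4])
  cbind(globalAvgPool(x), M)
}

#' @describeIn fuseFeatures gated modulation then global pooling.
#' @export
setMethod("fuseFeatures", "MetaBlockParams", function(params, xImg, xMeta)
  globalAvgPool(metaBlockForward(xImg, xMeta, params)))

#' @describeIn fuseFeatures channel reweighting then global pooling.
#' @export
setMethod("fuseFeatures", "MetaNetParams", function(params, xImg, xMeta)
  globalAvgPool(metaNetForward(xImg, xMeta, params)))

#' @describeIn fuseFeatures pooled, projected and concatenated streams.
#' @export
setMethod("fuseFeatures", "MDNetParams", function(params, xImg, xMeta)
  mdnetFuse(xImg, xMeta, params))

#' @describeIn fuseFeatures pooled features concatenated with metadata.
#' @export
setMethod("fuseFeatures", "ConcatFusion", function(params, xImg, xMeta)
  concatFuse(xImg, xMeta))

#' @describeIn fuseFeatures pooled image features only.
#' @export
setMethod("fuseFeatures", "NoneFusion", function(params, xImg, xMeta = NULL) {
  globalAvgPool(xImg)
})

#' @describeIn fusedDim MetaBlock: pooled modulated map, length `kImg`.
#' @export
setMethod("fusedDim", "MetaBlockParams", function(params, kImg, dMeta)
  ncol(params@Wf))
#' @describeIn fusedDim MetaNet: pooled reweighted map, length `kImg`.
#' @export
setMethod("fusedDim", "MetaNetParams", function(params, kImg, dMeta)
  ncol(params@W2))
#' @describeIn fusedDim MD-Net: two projected streams, `2*dFuse`.
#' @export
setMethod("fusedDim", "MDNetParams", function(params, kImg, dMeta)
  2L * params@dFuse)
#' @describeIn fusedDim Concatenation: `kImg + dMeta`.
#' @export
setMethod("fusedDim", "ConcatFusion", function(params, kImg, dMeta)
  as.integer(kImg + dMeta))
#' @describeIn fusedDim None: `kImg`.
#' @export
setMethod("fusedDim", "NoneFusion", function(params, kImg, dMeta)
  as.integer(kImg))

#' @describeIn dMeta metadata dimension the MetaBlock consumes.
#' @export
setMethod("dMeta", "MetaBlockParams", function(x) nrow(x@Wf))
#' @describeIn dMeta metadata dimension the MetaNet consumes.
#' @export
setMethod("dMeta", "MetaNetParams", function(x) nrow(x@W1))
#' @describeIn dMeta metadata dimension the MD-Net consumes.
#' @export
setMethod("dMeta", "MDNetParams", function(x) nrow(x@metablock@Wf))

#' @describeIn kImg channel count the MetaBlock modulates.
#' @export
setMethod("kImg", "MetaBlockParams", function(x) ncol(x@Wf))
#' @describeIn kImg channel count the MetaNet reweights.
#' @export
setMethod("kImg", "MetaNetParams", function(x) ncol(x@W2))
#' @describeIn kImg channel count the MD-Net consumes.
#' @export
setMethod("kImg", "MDNetParams", function(x) ncol(x@metablock@Wf))

setMethod("show", "MetaBlockParams", function(object)
  cat(sprintf("MetaBlockParams: d_meta = %d, k_img = %d\n",
              nrow(object@Wf), ncol(object@Wf))))
setMethod("show", "MetaNetParams", function(object)
  cat(sprintf("MetaNetParams: d_meta = %d, hidden = %d, k_img = %d\n",
              nrow(object@W1), ncol(object@W1), ncol(object@W2))))
setMethod("show", "MDNetParams", function(object)
  cat(sprintf("MDNetParams: d_meta = %d, k_img = %d, d_fuse = %d (fused length %d)\n",
              dMeta(object), kImg(object), object@dFuse, 2L * object@dFuse)))
setMethod("show", "ConcatFusion", function(object)
  cat("ConcatFusion: pooled image features ++ metadata vector\n"))
setMethod("show", "NoneFusion", function(object)
  cat("NoneFusion: pooled image features only (metadata ignored)\n"))
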