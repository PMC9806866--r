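#' Encoded metadata dimension of a schema or fusion block
#'
#' @param x a [MetadataSchema-class] or [FusionParams-class] object.
#' @return integer(1).
#' @export
setGeneric("dMeta", function(x) standardGeneric("dMeta"))

#' Image feature channel count
#'
#' @param x a [DenseBackbone-class] or parameterised
#'   [FusionParams-class] object.
#' @return integer(1), the number of feature-map channels `k_img`.
#' @export
setGeneric("kImg", function(x) standardGeneric("kImg"))

#' Run a backbone on a batch of images
#'
#' @param backbone a [DenseBackbone-class].
#' @param images numeric array `H x W x 3 x N` (or `H x W x 3` for a
#'   single image) with values on any finite scale.
#' @return feature map array `h x w x kImg x N`.
#' @export
setGeneric("extractFeatures",
           function(backbone, images) standardGeneric("extractFeatures"))

#' Fuse image features with metadata into a classifier input vector
#'
#' Dispatches on the fusion strategy: gated modulation then pooling
#' (MetaBlock), channel reweighting then pooling (MetaNet), the pooled
#' and projected combination of both (MD-Net), pooled features
#' concatenated with the metadata vector (Concatenation), or pooled
#' features alone (None).
#'
#' @param params a [FusionParams-class] object.
#' @param xImg feature map array `h x w x k x N` (or `h x w x k`).
#' @param xMeta encoded metadata: numeric vector of length `dMeta` or a
#'   `N x dMeta` matrix.  Ignored by `NoneFusion`.
#' @return `N x d` matrix of fused feature vectors.
#' @seealso [fusedDim()]
#' @export
setGeneric("fuseFeatures",
           function(params, xImg, xMeta = NULL) standardGeneric("fuseFeatures"))

#' Length of the fused feature vector a strategy produces
#'
#' @param params a [FusionParams-class] object.
#' @param kImg image channel count (needed by the parameter-free
#'   strategies).
#' @param dMeta encoded metadata dimension (needed by `ConcatFusion`).
#' @return integer(1).
#' @export
setGeneric("fusedDim",
           function(params, kImg, dMeta = 0L) standardGeneric("fusedDim"))
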