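#' @import methods
NULL

#' Metadata schema: ordered categorical fields and their one-hot layout
#'
#' A `MetadataSchema` fixes, once, the set of categorical fields and the
#' order of their categories, so that the one-hot encoding of a clinical
#' record is reproducible across sessions and machines.  The encoded
#' dimension `dMeta` is the sum of the per-field category counts.
#'
#' @slot fields named list; each element is a character vector of the
#'   field's categories in encoding order, the list names are the field
#'   names in encoding order.
#' @slot dMeta integer(1), total encoded dimension.
#'
#' @seealso [buildSchema()], [encodeRecord()], [encodeBatch()]
#' @export
setClass("MetadataSchema",
  representation(fields = "list", dMeta = "integer"),
  validity = function(object) {
    f <- object@fields
    if (length(f) == 0L) return("schema must declare at least one field")
    if (is.null(names(f)) || any(!nzchar(names(f))) || anyDuplicated(names(f)))
      return("fields must be a uniquely named list")
    for (nm in names(f)) {
      v <- f[[nm]]
      if (!is.character(v) || length(v) == 0L)
        return(sprintf("field '%s' has no categories", nm))
      if (anyDuplicated(v))
        return(sprintf("field '%s' has duplicated categories", nm))
    }
    if (object@dMeta != sum(lengths(f)))
      return("dMeta must equal the sum of per-field category counts")
    TRUE
  }
)

#' Fusion parameter classes
#'
#' `FusionParams` is the virtual parent of the five fusion strategies that
#' combine a convolutional feature map with an encoded metadata vector:
#'
#' * `MetaNetParams` — a two-layer subnetwork (affine, ReLU, affine,
#'   sigmoid) maps the metadata vector to one multiplicative scale in
#'   (0,1) per image channel.
#' * `MetaBlockParams` — affine maps of the metadata produce a
#'   per-channel scale (inside a tanh gate) and shift (inside a sigmoid
#'   gate) that modulate the feature map.
#' * `MDNetParams` — both blocks run side by side; each output is
#'   globally average-pooled, projected to a common dimension `dFuse`,
#'   and the two projections are concatenated.
#' * `ConcatFusion` — pooled image features concatenated with the raw
#'   metadata vector (no parameters).
#' * `NoneFusion` — pooled image features only; metadata is ignored.
#'
#' @name FusionParams-class
#' @aliases FusionParams MetaNetParams-class MetaBlockParams-class
#'   MDNetParams-class ConcatFusion-class NoneFusion-class
#' @seealso [metaBlockParams()], [metaNetParams()], [mdnetParams()],
#'   [concatFusion()], [noneFusion()], [fuseFeatures()]
NULL

#' @export
setClass("FusionParams", representation("VIRTUAL"))

#' @export
setClass("MetaBlockParams",
  contains = "FusionParams",
  representation(Wf = "matrix", Wg = "matrix", w0f = "numeric", w0g = "numeric"),
  validity = function(object) {
    d <- nrow(object@Wf); k <- ncol(object@Wf)
    if (!identical(dim(object@Wg), c(d, k)))
      return("Wf and Wg must share the same d_meta x k_img shape")
    if (length(object@w0f) != k || length(object@w0g) != k)
      return("bias vectors must have length k_img")
    if (!all(is.finite(object@Wf)) || !all(is.finite(object@Wg)) ||
        !all(is.finite(object@w0f)) || !all(is.finite(object@w0g)))
      return("parameters must be finite")
    TRUE
  }
)

#' @export
setClass("MetaNetParams",
  contains = "FusionParams",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric"),
  validity = function(object) {
    h <- ncol(object@W1)
    if (length(object@b1) != h) return("b1 must match the hidden width")
    if (nrow(object@W2) != h) return("W2 must consume the hidden layer")
    if (length(object@b2) != ncol(object@W2))
      return("b2 must have length k_img")
    TRUE
  }
)

#' @export
setClass("MDNetParams",
  contains = "FusionParams",
  representation(metanet = "MetaNetParams", metablock = "MetaBlockParams",
                 Pnet = "matrix", bnet = "numeric",
                 Pblock = "matrix", bblock = "numeric",
                 dFuse = "integer"),
  validity = function(object) {
    k <- ncol(object@metablock@Wf)
    if (ncol(object@metanet@W2) != k)
      return("metanet and metablock must target the same k_img")
    if (nrow(object@Pnet) != k || nrow(object@Pblock) != k)
      return("projections must consume k_img-dimensional pooled vectors")
    if (ncol(object@Pnet) != object@dFuse || ncol(object@Pblock) != object@dFuse)
      return("both projections must target the same dFuse")
    if (length(object@bnet) != object@dFuse || length(object@bblock) != object@dFuse)
      return("projection biases must have length dFuse")
    TRUE
  }
)

#' @export
setClass("ConcatFusion", contains = "FusionParams", representation())

#' @export
setClass("NoneFusion", contains = "FusionParams", representation())

#' Densely connected feature extractor
#'
#' A `DenseBackbone` is an ordered list of operations (convolutions,
#' average pools, densely connected blocks) mapping an RGB image batch,
#' stored as an `H x W x 3 x N` array, to a feature map
#' `h x w x kImg x N`.  Fusion blocks attach to this pre-pooling map.
#'
#' @slot name identifier of the architecture.
#' @slot ops list of operation descriptors (internal layout).
#' @slot kImg declared output channel count; always equals the channel
#'   count the forward pass actually produces.
#'
#' @seealso [loadPretrained()], [tinyDenseBackbone()], [extractFeatures()]
#' @export
setClass("DenseBackbone",
  representation(name = "character", ops = "list", kImg = "integer"),
  validity = function(object) {
    if (length(object@kImg) != 1L || object@kImg < 1L)
      return("kImg must be a positive scalar")
    TRUE
  }
)

#' Parameters of a single densely connected block
#'
#' Layer `l` of a dense block consumes the channel-concatenation of the
#' block input and all previous layers' outputs (`inChannels + (l-1) *
#' growth` channels) and emits `growth` new channels; the block output
#' concatenates the input with every layer's output, so it carries
#' `inChannels + L * growth` channels.
#'
#' @slot inChannels channels of the block input.
#' @slot growth channels added per layer.
#' @slot layers list of per-layer conv parameters (`w`, `b`).
#' @seealso [denseBlockParams()], [denseBlockForward()]
#' @export
setClass("DenseBlockParams",
  representation(inChannels = "integer", growth = "integer", layers = "list"),
  validity = function(object) {
    L <- length(object@layers)
    for (l in seq_len(L)) {
      w <- object@layers[[l]]$w
      if (dim(w)[3] != object@inChannels + (l - 1L) * object@growth)
        return(sprintf("layer %d must consume %d channels", l,
                       object@inChannels + (l - 1L) * object@growth))
      if (dim(w)[4] != object@growth)
        return(sprintf("layer %d must emit growth channels", l))
    }
    TRUE
  }
)

#' Image + metadata classification dataset
#'
#' Container for a set of RGB images with per-sample categorical
#' metadata and a class label, the in-memory form of the on-disk layout
#' `images/<id>.png` + `metadata.csv` used for both real and synthetic
#' data.
#'
#' @slot images numeric array `H x W x 3 x N`, values in \[0, 1\].
#' @slot meta data.frame with `N` rows of categorical metadata
#'   (character columns).
#' @slot labels factor of length `N`.
#' @slot provenance list; for synthetic data records the generator
#'   config, seed and per-sample template assignment.
#'
#' @seealso [generateDataset()], [readDataset()], [writeDataset()]
#' @export
setClass("LesionDataset",
  representation(images = "array", meta = "data.frame", labels = "factor",
                 provenance = "list"),
  validity = function(object) {
    d <- dim(object@images)
    if (length(d) != 4L || d[3] != 3L)
      return("images must be an H x W x 3 x N array")
    n <- d[4]
    if (nrow(object@meta) != n) return("meta must have one row per image")
    if (length(object@labels) != n) return("labels must have one entry per image")
    TRUE
  }
)

#' Assembled classification model
#'
#' Bundles a feature-extracting backbone, a fusion strategy, a linear
#' softmax classifier on the fused feature vector, and the metadata
#' schema the fusion parameters were shaped against.
#'
#' @slot backbone a [DenseBackbone-class].
#' @slot fusion a [FusionParams-class] strategy.
#' @slot classifier list with weight matrix `W` (d x C) and bias `b`.
#' @slot classes character vector of class labels, fixing column order
#'   of predicted probabilities.
#' @slot schema a [MetadataSchema-class], or `NULL` for image-only
#'   models.
#' @slot dropout dropout rate applied to the fused vector during
#'   training only.
#'
#' @seealso [metaFuseModel()], [fitModel()], [evaluateModel()]
#' @export
setClass("MetaFuseModel",
  representation(backbone = "DenseBackbone", fusion = "FusionParams",
                 classifier = "list", classes = "character",
                 schema = "ANY", dropout = "numeric"),
  validity = function(object) {
    if (length(object@classes) < 2L) return("need at least two classes")
    if (!is.matrix(object@classifier$W) ||
        ncol(object@classifier$W) != length(object@classes))
      return("classifier W must have one column per class")
    if (length(object@classifier$b) != length(object@classes))
      return("classifier bias must have one entry per class")
    if (object@dropout < 0 || object@dropout >= 1)
      return("dropout must lie in [0, 1)")
    TRUE
  }
)

#' Evaluation report
#'
#' Confusion matrix and the derived metric suite.  Sensitivity and
#' specificity are macro one-vs-rest averages; `bacc` is their mean,
#' the primary index for imbalanced data; `baccRecall` is plain macro
#' recall, reported alongside because the binary definitions coincide
#' but the multiclass extensions differ.
#'
#' @slot accuracy overall accuracy.
#' @slot sensitivity macro-averaged sensitivity (recall).
#' @slot specificity macro-averaged specificity.
#' @slot bacc (sensitivity + specificity) / 2.
#' @slot baccRecall macro recall.
#' @slot auc macro one-vs-rest ROC AUC (`NA` when no scores supplied).
#' @slot perClass data.frame of per-class sensitivity/specificity.
#' @slot confusion the confusion matrix (rows = truth).
#' @export
setClass("MetricsReport",
  representation(accuracy = "numeric", sensitivity = "numeric",
                 specificity = "numeric", bacc = "numeric",
                 baccRecall = "numeric", auc = "numeric",
                 perClass = "data.frame", confusion = "matrix"))
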