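## Training protocol: stratified 3:1 splitting, flip/colour-jitter
## augmentation, mini-batch cross-entropy training with plateau LR
## halving and early stopping, both driven by validation balanced
## accuracy (the primary index).

#' Training configuration
#'
#' Defaults follow the reference protocol: batch size 30, at most 150
#' epochs, learning rate halved after 10 epochs without validation
#' improvement, training stopped after 15, a 3:1 train:test ratio
#' handled by [splitDataset()], and flip/brightness/contrast/saturation
#' augmentation on training samples only.  The optimizer is Adam with
#' initial learning rate 0.001.
#'
#' @param batchSize mini-batch size.
#' @param maxEpochs epoch cap.
#' @param lr initial learning rate.
#' @param lrPatience epochs without validation-BACC improvement before
#'   the learning rate is multiplied by `lrFactor`.
#' @param lrFactor multiplicative reduction factor, in (0, 1).
#' @param stopPatience epochs without improvement before early stop;
#'   use `Inf` to disable.
#' @param seed seed for shuffling, augmentation and dropout.
#' @param valFraction fraction of the training portion held out for
#'   validation when no validation set is supplied to [fitModel()].
#' @param minDelta minimum increase in validation BACC that counts as
#'   an improvement.
#' @param augment logical, apply augmentation to training batches.
#' @param hFlip,vFlip flip probabilities.
#' @param brightness,contrast,saturation jitter half-ranges (0
#'   disables a jitter).
#' @param classWeights logical; weight the loss by inverse class
#'   frequency (off by default — imbalance is otherwise handled only by
#'   reporting BACC).
#' @param freezeBackbone logical; train only fusion + classifier.
#' @param verbose print per-epoch progress.
#' @return a list of class `"trainConfig"`.
#' @export
trainConfig <- function(batchSize = 30L, maxEpochs = 150L, lr = 0.001,
                        lrPatience = 10L, lrFactor = 0.5,
                        stopPatience = 15L, seed = 1L, valFraction = 0.2,
                        minDelta = 1e-8, augment = TRUE,
                        hFlip = 0.5, vFlip = 0.5, brightness = 0.2,
                        contrast = 0.2, saturation = 0.2,
                        classWeights = FALSE, freezeBackbone = FALSE,
                        verbose = FALSE) {
  stopifnot(batchSize >= 1, maxEpochs >= 0, lr > 0,
            lrFactor > 0, lrFactor < 1, lrPatience >= 1, stopPatience >= 1,
            valFraction > 0, valFraction < 1)
  structure(list(batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs), lr = lr,
                 lrPatience = as.integer(lrPatience), lrFactor = lrFactor,
                 stopPatience = stopPatience, seed = as.integer(seed),
                 valFraction = valFraction, minDelta = minDelta,
                 augment = isTRUE(augment), hFlip = hFlip, vFlip = vFlip,
                 brightness = brightness, contrast = contrast,
                 saturation = saturation, classWeights = isTRUE(classWeights),
                 freezeBackbone = isTRUE(freezeBackbone),
                 verbose = isTRUE(verbose)),
            class = "trainConfig")
}

#' Split a dataset into train and test portions
#'
#' Deterministic for a fixed seed.  With `stratify = TRUE` (default)
#' the per-class proportions are preserved within rounding, so a 3:1
#' split of 40 A + 20 B yields 30/10 A and 15/5 B.
#'
#' @param data a [LesionDataset-class].
#' @param ratio train fraction in (0, 1); 0.75 realises the 3:1
#'   train:test protocol.
#' @param seed integer seed.
#' @param stratify preserve class proportions.
#' @return list with elements `train` and `test` (disjoint, exhaustive).
#' @export
splitDataset <- function(data, ratio = 0.75, seed = 1L, stratify = TRUE) {
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1)
    stop("ratio must lie strictly between 0 and 1 (train fraction)")
  n <- length(data)
  if (n < 2L) stop("need at least 2 samples to split")
  trainIdx <- withSeed(seed, {
    if (stratify) {
      lab <- droplevels(data@labels)
      counts <- table(lab)
      if (any(counts < 1L)) stop("every class needs at least one sample")
      # per-class floor allocation, remainder spread by largest fraction
      # so the overall train size is exactly round(n * ratio)
      exact <- as.numeric(counts) * ratio
      take <- floor(exact)
      short <- round(n * ratio) - sum(take)
      if (short > 0) {
        extra <- order(exact - take, decreasing = TRUE)[seq_len(short)]
        take[extra] <- take[extra] + 1L
      }
      take <- pmin(pmax(take, ifelse(counts > 1L, 1L, counts)), counts)
      unlist(lapply(seq_along(levels(lab)), function(i) {
        idx <- which(lab == levels(lab)[i])
        if (length(idx) == 1L) idx else sample(idx, take[i])
      }), use.names = FALSE)
    } else sample(n, round(n * ratio))
  })
  trainIdx <- sort(trainIdx)
  list(train = data[trainIdx], test = data[setdiff(seq_len(n), trainIdx)])
}

#' Randomly augment one RGB image
#'
#' Applies, in order: horizontal flip (probability `hFlip`), vertical
#' flip (`vFlip`), then brightness shift, contrast scaling and
#' saturation scaling drawn uniformly from ±the given half-ranges.  A
#' probability or half-range of 0 skips that step without consuming
#' random numbers, so the all-zero configuration is the exact
#' identity.  Output dimensions always equal input dimensions, and the
#' result is deterministic given the RNG state.
#'
#' @param img numeric array `H x W x 3`, values in \[0, 1\].
#' @param hFlip,vFlip flip probabilities.
#' @param brightness,contrast,saturation jitter half-ranges.
#' @return augmented image, same shape, clamped to \[0, 1\].
#' @export
augmentImage <- function(img, hFlip = 0.5, vFlip = 0.5, brightness = 0.2,
                         contrast = 0.2, saturation = 0.2) {
  if (hFlip > 0 && stats::runif(1) < hFlip)
    img <- img[, dim(img)[2]:1, , drop = FALSE]
  if (vFlip > 0 && stats::runif(1) < vFlip)
    img <- img[dim(img)[1]:1, , , drop = FALSE]
  jitter <- FALSE
  if (brightness > 0) {
    img <- img + stats::runif(1, -brightness, brightness); jitter <- TRUE
  }
  if (contrast > 0) {
    mu <- mean(img)
    img <- (img - mu) * (1 + stats::runif(1, -contrast, contrast)) + mu
    jitter <- TRUE
  }
  if (saturation > 0) {
    gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    fac <- 1 + stats::runif(1, -saturation, saturation)
    img <- array(rep(gray, 3L), dim(img)) * (1 - fac) + img * fac
    jitter <- TRUE
  }
  if (jitter) img <- pmin(pmax(img, 0), 1)
  img
}

sinceImprovement <- function(valBacc, minDelta = 1e-8) {
  best <- -Inf
  lastImprove <- 0L
  for (i in seq_along(valBacc)) {
    if (valBacc[i] > best + minDelta || i == 1L) {
      best <- max(best, valBacc[i]); lastImprove <- i
    }
  }
  length(valBacc) - lastImprove
}

#' Plateau learning-rate schedule step
#'
#' Returns `currentLr * lrFactor` when the best validation BACC has
#' not improved for `lrPatience` consecutive epochs *and* at least
#' `lrPatience` epochs have been run at the current learning rate
#' (so one plateau triggers exactly one halving); otherwise returns
#' `currentLr` unchanged.  After `n` triggered reductions the rate is
#' exactly `lr0 * lrFactor^n`.
#'
#' @param history data.frame with one row per completed epoch and
#'   columns `valBacc` and `lr` (the rate the epoch ran at).
#' @param currentLr learning rate in effect.
#' @param config a [trainConfig()].
#' @return the learning rate for the next epoch.
#' @export
lrScheduleStep <- function(history, currentLr, config = trainConfig()) {
  if (nrow(history) == 0L) return(currentLr)
  since <- sinceImprovement(history$valBacc, config$minDelta)
  changes <- which(diff(history$lr) != 0)
  epochsAtLr <- if (length(changes)) nrow(history) - max(changes) else nrow(history)
  if (since >= config$lrPatience && epochsAtLr >= config$lrPatience)
    currentLr * config$lrFactor
  else currentLr
}

#' Early-stopping check
#'
#' @inheritParams lrScheduleStep
#' @return `TRUE` when validation BACC has not improved for
#'   `stopPatience` consecutive epochs.
#' @export
earlyStopCheck <- function(history, config = trainConfig()) {
  if (nrow(history) == 0L) return(FALSE)
  sinceImprovement(history$valBacc, config$minDelta) >= config$stopPatience
}

#' Assemble a classification model
#'
#' @param backbone a [DenseBackbone-class] feature extractor.
#' @param fusion a [FusionParams-class] strategy whose `kImg` (if
#'   parameterised) must match the backbone.
#' @param classes character vector of class labels.
#' @param schema the [MetadataSchema-class] the fusion consumes;
#'   `NULL` only for [noneFusion()].
#' @param dropout dropout rate on the fused vector during training.
#' @param seed seed for the classifier initialization.
#' @return a [MetaFuseModel-class].
#' @export
metaFuseModel <- function(backbone, fusion, classes, schema = NULL,
                          dropout = 0.5, seed = 1L) {
  dM <- if (is.null(schema)) 0L else dMeta(schema)
  if (!is(fusion, "NoneFusion") && is.null(schema))
    stop("this fusion strategy needs a metadata schema")
  d <- fusedDim(fusion, kImg(backbone), dM)
  cls <- withSeed(seed, list(
    W = matrix(uniformInit(d * length(classes), d), d, length(classes)),
    b = numeric(length(classes))))
  new("MetaFuseModel", backbone = backbone, fusion = fusion,
      classifier = cls, classes = as.character(classes), schema = schema,
      dropout = dropout)
}

setMethod("show", "MetaFuseModel", function(object) {
  cat("MetaFuseModel\n  backbone: "); show(object@backbone)
  cat("  fusion:   "); show(object@fusion)
  cat(sprintf("  classes:  %s\n", paste(object@classes, collapse = ", ")))
  cat(sprintf("  dropout:  %.2f\n", object@dropout))
})

encodeDatasetMeta <- function(model, data) {
  if (is(model@fusion, "NoneFusion")) {
    matrix(0, length(data), 0L)
  } else {
    encodeBatch(data@meta, model@schema)
  }
}

labelIndices <- function(model, data) {
  y <- match(as.character(data@labels), model@classes)
  if (anyNA(y))
    stop("dataset contains label(s) outside the model's class set: ",
         paste(unique(as.character(data@labels)[is.na(y)]), collapse = ", "))
  y
}

#' Predicted class probabilities
#'
#' Deterministic forward pass (no augmentation, no dropout).
#'
#' @param model a [MetaFuseModel-class].
#' @param data a [LesionDataset-class].
#' @param batchSize forward batch size.
#' @return `N x C` matrix of softmax probabilities, columns in
#'   `model@classes` order.
#' @export
predictProbs <- function(model, data, batchSize = 128L) {
  n <- length(data)
  M <- encodeDatasetMeta(model, data)
  out <- matrix(0, n, length(model@classes),
                dimnames = list(NULL, model@classes))
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    fwd <- modelForward(model, data@images[, , , idx, drop = FALSE],
                        M[idx, , drop = FALSE], train = FALSE)
    out[idx, ] <- softmaxProbs(fwd$logits)
  }
  out
}

#' Train an assembled model
#'
#' Minimises multiclass cross-entropy with Adam over mini-batches,
#' applying augmentation to training samples only.  After each epoch
#' the model is scored on the validation set by balanced accuracy;
#' that score drives plateau learning-rate halving
#' ([lrScheduleStep()]) and early stopping ([earlyStopCheck()]), and
#' the parameters of the best validation epoch are restored at the
#' end.  Fully deterministic for a fixed `config$seed` in
#' single-threaded execution.
#'
#' @param model a [MetaFuseModel-class].
#' @param data training [LesionDataset-class].
#' @param config a [trainConfig()].
#' @param valData optional validation set; when `NULL`, a stratified
#'   `config$valFraction` of `data` is held out.
#' @return list with `model` (best-epoch parameters), `history`
#'   (data.frame: epoch, loss, lr, valBacc), `bestEpoch` and
#'   `stoppedEpoch`.
#' @export
fitModel <- function(model, data, config = trainConfig(), valData = NULL) {
  set.seed(config$seed)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        lr = numeric(), valBacc = numeric())
  if (config$maxEpochs == 0L)
    return(list(model = model, history = history, bestEpoch = NA_integer_,
                stoppedEpoch = 0L))
  if (is.null(valData)) {
    sp <- splitDataset(data, ratio = 1 - config$valFraction,
                       seed = config$seed + 1L, stratify = TRUE)
    data <- sp$train; valData <- sp$test
  }
  n <- length(data)
  if (n < 1L || length(valData) < 1L) stop("need non-empty train and validation sets")
  M <- encodeDatasetMeta(model, data)
  y <- labelIndices(model, data)
  valM <- encodeDatasetMeta(model, valData)
  valY <- as.character(valData@labels)
  wts <- NULL
  if (config$classWeights) {
    freq <- table(factor(model@classes[y], levels = model@classes))
    wcl <- sum(freq) / (length(freq) * pmax(as.numeric(freq), 1))
    wts <- wcl[y]
  }
  params <- modelParamTree(model, config$freezeBackbone)
  opt <- adamInit(params)
  lr <- config$lr
  best <- -Inf; bestParams <- params; bestEpoch <- NA_integer_
  for (epoch in seq_len(config$maxEpochs)) {
    ord <- sample(n)
    epochLoss <- 0
    for (start in seq(1L, n, by = config$batchSize)) {
      idx <- ord[start:min(start + config$batchSize - 1L, n)]
      xb <- data@images[, , , idx, drop = FALSE]
      if (config$augment) {
        for (j in seq_along(idx))
          xb[, , , j] <- augmentImage(xb[, , , j], config$hFlip, config$vFlip,
                                      config$brightness, config$contrast,
                                      config$saturation)
      }
      model <- setModelParamTree(model, params)
      fwd <- modelForward(model, xb, M[idx, , drop = FALSE],
                          train = TRUE, cache = TRUE)
      ce <- crossEntropy(fwd$logits, y[idx],
                         if (is.null(wts)) NULL else wts[idx])
      if (!is.finite(ce$loss))
        stop(sprintf("training diverged: non-finite loss at epoch %d (lr %g)",
                     epoch, lr))
      grads <- modelBackward(model, fwd, M[idx, , drop = FALSE],
                             ce$glogits, config$freezeBackbone)
      upd <- adamStep(params, grads, opt, lr)
      params <- upd$params; opt <- upd$state
      epochLoss <- epochLoss + ce$loss * length(idx)
    }
    model <- setModelParamTree(model, params)
    valPred <- model@classes[max.col(predictProbs(model, valData),
                                     ties.method = "first")]
    vb <- suppressWarnings(
      balancedAccuracy(confusionCounts(valY, valPred, model@classes)))
    history <- rbind(history, data.frame(epoch = epoch,
                                         loss = epochLoss / n,
                                         lr = lr, valBacc = vb))
    if (vb > best + config$minDelta || is.na(bestEpoch)) {
      if (vb > best) { best <- vb; bestParams <- params; bestEpoch <- epoch }
    }
    if (config$verbose)
      message(sprintf("epoch %3d  loss %.4f  lr %.2e  val BACC %.4f",
                      epoch, epochLoss / n, lr, vb))
    if (earlyStopCheck(history, config)) break
    lr <- lrScheduleStep(history, lr, config)
  }
  model <- setModelParamTree(model, bestParams)
  list(model = model, history = history, bestEpoch = bestEpoch,
       stoppedEpoch = nrow(history))
}

#' Evaluate a model on a test set
#'
#' Deterministic forward pass, then the full metric suite with BACC as
#' the primary index.
#'
#' @param model a trained [MetaFuseModel-class].
#' @param data a non-empty [LesionDataset-class].
#' @return a [MetricsReport-class].
#' @export
evaluateModel <- function(model, data) {
  if (length(data) == 0L) stop("cannot evaluate on an empty test set")
  probs <- predictProbs(model, data)
  pred <- model@classes[max.col(probs, ties.method = "first")]
  suppressWarnings(metricsReport(as.character(data@labels), pred,
                                 scores = probs, classes = model@classes))
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores all parameters plus a JSON manifest sidecar
#' (`<path>.json`) recording the architecture dimensions (`d_meta`,
#' `k_img`, `d_fuse`, hidden width), class set and the metadata schema
#' hash, so loading can verify it matches the expected setup.
#'
#' @param model a [MetaFuseModel-class].
#' @param path checkpoint file path.
#' @param config optional [trainConfig()] stored alongside.
#' @return `saveCheckpoint` returns `path` invisibly; `loadCheckpoint`
#'   the restored model (with the stored config as attribute
#'   `"config"`).
#' @export
saveCheckpoint <- function(model, path, config = NULL) {
  manifest <- list(
    backbone = model@backbone@name,
    k_img = kImg(model@backbone),
    fusion = class(model@fusion)[1],
    d_meta = if (is.null(model@schema)) 0L else dMeta(model@schema),
    d_fuse = if (is(model@fusion, "MDNetParams")) model@fusion@dFuse else NA,
    hidden = if (is(model@fusion, "MetaNetParams")) ncol(model@fusion@W1)
             else if (is(model@fusion, "MDNetParams")) ncol(model@fusion@metanet@W1)
             else NA,
    classes = model@classes,
    schema_hash = if (is.null(model@schema)) NA else schemaHash(model@schema))
  saveRDS(list(model = model, config = config, manifest = manifest), path)
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  model <- ck$model
  validObject(model)
  if (!is.null(model@schema) &&
      !identical(schemaHash(model@schema), ck$manifest$schema_hash))
    stop("checkpoint manifest does not match its stored schema")
  attr(model, "config") <- ck$config
  model
}
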