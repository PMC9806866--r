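## Synthetic image+metadata benchmark generator.  Each class owns a
## procedural texture/colour template (oriented sinusoidal stripes with
## a class-specific hue); a designated categorical metadata field can
## confound the class-to-template assignment, so that the same image
## pattern maps to different classes under different metadata values
## and the metadata carries genuine class signal.  The generative
## table is simple enough that the optimal (Bayes) balanced accuracy
## with and without metadata is computable by enumeration.

#' Synthetic dataset configuration
#'
#' @param nSamples number of samples (class counts balanced within 1).
#' @param nClasses number of classes `C` (at most 12 distinguishable
#'   templates).
#' @param imageSize square image side in pixels.
#' @param metaFields named list of category vectors, the categorical
#'   metadata fields to draw (uniformly, independently of the class).
#' @param confoundField name of the field that confounds the
#'   class-to-template assignment (its j-th category rotates the
#'   assignment by j-1; the first category leaves it unchanged).
#' @param metaEffect lambda in \[0, 1\]: per-sample probability that
#'   the rendered template is determined jointly by (class, confounder
#'   value) rather than by the class alone.  At 0 the metadata carries
#'   no class information given the image; at 1 a binary confounder
#'   makes image-only classification fall to chance on the confounded
#'   class pairs while (image, metadata) determines the class exactly.
#' @param noiseSd standard deviation of the Gaussian pixel noise.
#' @param seed generator seed.
#' @return a list of class `"synthConfig"`.
#' @export
synthConfig <- function(nSamples = 200L, nClasses = 4L, imageSize = 32L,
                        metaFields = list(sex = c("female", "male"),
                                          region = c("arm", "face", "hand", "trunk")),
                        confoundField = "sex", metaEffect = 0.5,
                        noiseSd = 0.05, seed = 1L) {
  stopifnot(metaEffect >= 0, metaEffect <= 1, nSamples >= nClasses,
            noiseSd >= 0, imageSize >= 8)
  if (nClasses > 12L)
    stop("at most 12 distinct class templates are supported")
  if (!confoundField %in% names(metaFields))
    stop("confoundField '", confoundField, "' is not a declared metadata field")
  structure(list(nSamples = as.integer(nSamples),
                 nClasses = as.integer(nClasses),
                 imageSize = as.integer(imageSize),
                 metaFields = lapply(metaFields, as.character),
                 confoundField = confoundField,
                 metaEffect = metaEffect, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "synthConfig")
}

## oriented stripe template with a class-specific hue, values in [0,1]
renderTemplate <- function(t, nTemplates, size) {
  theta <- (t - 1) * pi / nTemplates
  hue <- (t - 1) / nTemplates
  xy <- seq(0, 1, length.out = size)
  phase <- outer(xy, xy, function(x, y) x * cos(theta) + y * sin(theta))
  pattern <- 0.5 + 0.5 * sin(2 * pi * 4 * phase)
  col <- grDevices::col2rgb(grDevices::hsv(hue, 0.8, 0.9))[, 1] / 255
  bg <- 0.1
  img <- array(0, c(size, size, 3L))
  for (k in 1:3) img[, , k] <- bg + pattern * (col[k] - bg)
  img
}

classLabels <- function(C) sprintf("class_%d", seq_len(C))

#' Generate a synthetic image+metadata dataset
#'
#' Class labels are assigned balanced within one sample; metadata
#' fields are drawn uniformly.  With probability `metaEffect` a
#' sample's rendered template index is the class index rotated by the
#' confounder category index (so the image pattern alone no longer
#' identifies the class); otherwise it is the class index itself.
#' Gaussian pixel noise is added and values clamped to \[0, 1\].
#' Byte-identical output for a fixed seed.
#'
#' @param config a [synthConfig()].
#' @return a [LesionDataset-class]; `provenance` records the config,
#'   seed and per-sample template assignment.
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "synthConfig"))
  C <- config$nClasses; n <- config$nSamples; size <- config$imageSize
  withSeed(config$seed, {
    labels <- sample(rep_len(seq_len(C), n))
    meta <- as.data.frame(lapply(config$metaFields, function(cats)
      sample(cats, n, replace = TRUE)), stringsAsFactors = FALSE)
    names(meta) <- names(config$metaFields)
    confCats <- config$metaFields[[config$confoundField]]
    v <- match(meta[[config$confoundField]], confCats)
    confounded <- stats::runif(n) < config$metaEffect
    templates <- ifelse(confounded,
                        ((labels - 1L + (v - 1L)) %% C) + 1L,
                        labels)
    base <- lapply(seq_len(C), renderTemplate, nTemplates = C, size = size)
    images <- array(0, c(size, size, 3L, n))
    for (i in seq_len(n)) {
      img <- base[[templates[i]]]
      if (config$noiseSd > 0)
        img <- img + stats::rnorm(length(img), 0, config$noiseSd)
      images[, , , i] <- pmin(pmax(img, 0), 1)
    }
    lesionDataset(images, meta,
                  factor(classLabels(C)[labels], levels = classLabels(C)),
                  provenance = list(seed = config$seed,
                                    metaEffect = config$metaEffect,
                                    noiseSd = config$noiseSd,
                                    nClasses = C, imageSize = size,
                                    confoundField = config$confoundField,
                                    templates = templates,
                                    ids = sprintf("img_%05d", seq_len(n))))
  })
}

#' Optimal (Bayes) balanced accuracy with and without metadata
#'
#' Enumerates the generative table over (class, confounder value,
#' template) and scores the maximum-a-posteriori rule that sees either
#' the template alone (image only) or the template plus the confounder
#' value.  Pixel noise is assumed small enough that the template is
#' recoverable from the image (the templates' hues are well separated;
#' the assumption holds comfortably for `noiseSd` up to about 0.15),
#' so the returned rates are exact for the template-level decision
#' problem.  The gap between the two rates is non-decreasing in
#' `metaEffect` and zero at `metaEffect = 0`.
#'
#' @param config a [synthConfig()].
#' @return named numeric vector `c(imageOnly, withMeta)` of Bayes
#'   balanced accuracies.
#' @export
bayesRates <- function(config) {
  stopifnot(inherits(config, "synthConfig"))
  C <- config$nClasses
  V <- length(config$metaFields[[config$confoundField]])
  lam <- config$metaEffect
  ## joint p(c, v, t), all indices 1-based
  p <- array(0, c(C, V, C))
  for (c in seq_len(C)) for (v in seq_len(V)) {
    tConf <- ((c - 1L + (v - 1L)) %% C) + 1L
    p[c, v, tConf] <- p[c, v, tConf] + lam / (C * V)
    p[c, v, c] <- p[c, v, c] + (1 - lam) / (C * V)
  }
  baccOfRule <- function(pred) {   # pred[v, t] or pred[t] (v ignored)
    cm <- matrix(0, C, C)
    for (c in seq_len(C)) for (v in seq_len(V)) for (t in seq_len(C)) {
      if (p[c, v, t] == 0) next
      pr <- if (is.matrix(pred)) pred[v, t] else pred[t]
      cm[c, pr] <- cm[c, pr] + p[c, v, t]
    }
    sens <- diag(cm) / rowSums(cm)
    neg <- sum(cm) - rowSums(cm)
    fp <- colSums(cm) - diag(cm)
    spec <- (neg - fp) / neg
    (mean(sens) + mean(spec)) / 2
  }
  ## MAP rules (ties broken toward the smallest class index)
  predImg <- vapply(seq_len(C), function(t)
    which.max(apply(p[, , t, drop = FALSE], 1L, sum)), 1L)
  predMeta <- matrix(0L, V, C)
  for (v in seq_len(V)) for (t in seq_len(C))
    predMeta[v, t] <- which.max(p[, v, t])
  c(imageOnly = baccOfRule(predImg), withMeta = baccOfRule(predMeta))
}
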