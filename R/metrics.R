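## Evaluation suite: confusion matrix, accuracy, macro one-vs-rest
## sensitivity/specificity, balanced accuracy (the primary index) and
## macro ROC AUC.

#' Confusion matrix of predicted against true labels
#'
#' @param truth,predicted label vectors of equal length; every value
#'   must belong to `classes`.
#' @param classes character vector fixing row/column order; defaults to
#'   the sorted union of observed labels.
#' @return `C x C` integer matrix, rows = true class, columns =
#'   predicted class.
#' @export
confusionCounts <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (is.null(classes)) classes <- sortC(unique(c(truth, predicted)))
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad))
    stop("label(s) outside the declared class set: ",
         paste(bad, collapse = ", "))
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

#' Overall accuracy from a confusion matrix
#'
#' Multiclass generalization of `(TP + TN) / (TP + FP + FN + TN)`: the
#' trace over the total count.
#'
#' @param cm square confusion matrix (rows = truth).
#' @return accuracy in \[0, 1\].
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("cannot compute accuracy of an empty confusion matrix")
  sum(diag(cm)) / total
}

#' Macro-averaged sensitivity and specificity
#'
#' Each class `c` is treated one-vs-rest: sensitivity (recall) is
#' `TP / (TP + FN)` and specificity `TN / (FP + TN)`; the unweighted
#' means over classes are returned.  A class with no true samples
#' contributes no sensitivity term (and one with no negatives no
#' specificity term); such classes are excluded with a warning.
#'
#' @param cm square confusion matrix (rows = truth).
#' @return named numeric vector `c(sensitivity, specificity)`, with the
#'   per-class values in `attr(, "perClass")`.
#' @export
sensitivitySpecificity <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  C <- nrow(cm)
  if (is.null(rownames(cm)))
    rownames(cm) <- colnames(cm) <- as.character(seq_len(C))
  tp <- diag(cm)
  rowTot <- rowSums(cm)   # TP + FN
  colTot <- colSums(cm)   # TP + FP
  fp <- colTot - tp
  neg <- total - rowTot   # TN + FP
  sens <- ifelse(rowTot > 0, tp / rowTot, NA_real_)
  spec <- ifelse(neg > 0, (neg - fp) / neg, NA_real_)
  if (anyNA(sens))
    warning("class(es) without true samples excluded from sensitivity: ",
            paste(rownames(cm)[is.na(sens)], collapse = ", "))
  if (anyNA(spec))
    warning("class(es) without negative samples excluded from specificity: ",
            paste(rownames(cm)[is.na(spec)], collapse = ", "))
  out <- c(sensitivity = mean(sens, na.rm = TRUE),
           specificity = mean(spec, na.rm = TRUE))
  attr(out, "perClass") <- data.frame(class = rownames(cm),
                                      sensitivity = sens, specificity = spec,
                                      row.names = NULL)
  out
}

#' Balanced accuracy
#'
#' `(sensitivity + specificity) / 2` with macro one-vs-rest averages —
#' the primary evaluation index for imbalanced class distributions.
#' Invariant to per-class duplication of samples.
#'
#' @param cm square confusion matrix (rows = truth).
#' @return balanced accuracy in \[0, 1\].
#' @export
balancedAccuracy <- function(cm) {
  ss <- sensitivitySpecificity(cm)
  unname((ss["sensitivity"] + ss["specificity"]) / 2)
}

#' Macro one-vs-rest ROC AUC
#'
#' Rank-based (Mann-Whitney) AUC per class against its score column,
#' ties contributing 1/2, macro-averaged over classes present in the
#' truth with at least one negative.  Equivalent to the trapezoidal
#' area under the ROC curve.
#'
#' @param truth label vector.
#' @param scores numeric matrix, one column per class (column names or
#'   `classes` fix the correspondence), one row per sample.
#' @param classes optional class order; defaults to `colnames(scores)`.
#' @return macro AUC in \[0, 1\].
#' @export
aucMacro <- function(truth, scores, classes = colnames(scores)) {
  truth <- as.character(truth)
  scores <- as.matrix(scores)
  if (is.null(classes)) stop("scores must have column names or classes must be given")
  if (nrow(scores) != length(truth))
    stop("scores must have one row per sample")
  if (!all(is.finite(scores))) stop("scores must be finite")
  aucs <- numeric(0)
  skipped <- character(0)
  for (j in seq_along(classes)) {
    pos <- truth == classes[j]
    nPos <- sum(pos); nNeg <- sum(!pos)
    if (nPos == 0L || nNeg == 0L) { skipped <- c(skipped, classes[j]); next }
    r <- rank(scores[, j])
    aucs <- c(aucs, (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg))
  }
  if (length(skipped))
    warning("class(es) absent from truth (or covering all of it) excluded from AUC: ",
            paste(skipped, collapse = ", "))
  if (length(aucs) == 0L) stop("no class with both positives and negatives")
  mean(aucs)
}

#' Full evaluation report
#'
#' @param truth,predicted label vectors.
#' @param scores optional `N x C` score matrix for the AUC.
#' @param classes optional class order.
#' @return a [MetricsReport-class].
#' @export
metricsReport <- function(truth, predicted, scores = NULL, classes = NULL) {
  if (is.null(classes))
    classes <- if (!is.null(scores) && !is.null(colnames(scores)))
      colnames(scores) else sortC(unique(c(as.character(truth),
                                           as.character(predicted))))
  cm <- confusionCounts(truth, predicted, classes)
  ss <- sensitivitySpecificity(cm)
  auc <- if (is.null(scores)) NA_real_ else aucMacro(truth, scores, classes)
  new("MetricsReport",
      accuracy = accuracy(cm),
      sensitivity = unname(ss["sensitivity"]),
      specificity = unname(ss["specificity"]),
      bacc = unname((ss["sensitivity"] + ss["specificity"]) / 2),
      baccRecall = unname(ss["sensitivity"]),
      auc = auc,
      perClass = attr(ss, "perClass"),
      confusion = cm)
}

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  cat(sprintf("  accuracy     %.4f\n", object@accuracy))
  cat(sprintf("  sensitivity  %.4f (macro)\n", object@sensitivity))
  cat(sprintf("  specificity  %.4f (macro)\n", object@specificity))
  cat(sprintf("  BACC         %.4f  [primary index]\n", object@bacc))
  cat(sprintf("  macro recall %.4f\n", object@baccRecall))
  if (!is.na(object@auc)) cat(sprintf("  AUC          %.4f (macro)\n", object@auc))
  cat("  confusion (rows = truth):\n")
  print(object@confusion)
})

#' Serialize a metrics report
#'
#' Writes the scalar metrics and per-class table as JSON, and
#' optionally the confusion matrix as CSV.
#'
#' @param report a [MetricsReport-class].
#' @param path JSON output path.
#' @param confusionCsv optional CSV path for the confusion matrix.
#' @return `path`, invisibly.
#' @export
writeMetrics <- function(report, path, confusionCsv = NULL) {
  jsonlite::write_json(list(
    accuracy = report@accuracy, sensitivity = report@sensitivity,
    specificity = report@specificity, bacc = report@bacc,
    bacc_recall = report@baccRecall, auc = report@auc,
    per_class = report@perClass), path, auto_unbox = TRUE, digits = NA,
    na = "null")
  if (!is.null(confusionCsv))
    utils::write.csv(report@confusion, confusionCsv)
  invisible(path)
}
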