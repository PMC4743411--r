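# Classification metrics: MCC, Cohen's kappa, AUC and macro-averaging.
# Implemented from their defining formulas; cross-checked against
# independent implementations in the test suite.

#' Matthews correlation coefficient from confusion counts
#'
#' `MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, defined as
#' 0 when the denominator vanishes.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return Numeric value in \[-1, 1\].
#' @export
mcc <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  denom <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (denom == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
}

#' MCC from binary truth/prediction vectors
#' @param truth,pred Binary vectors (0/1).
#' @return Numeric value in \[-1, 1\].
#' @export
mcc_from_labels <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  mcc(sum(truth == 1 & pred == 1), sum(truth == 0 & pred == 0),
      sum(truth == 0 & pred == 1), sum(truth == 1 & pred == 0))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between predicted and true classes, computed
#' from a square confusion matrix (rows = truth, columns = prediction) or
#' from two class vectors.
#'
#' @param truth Confusion matrix, or truth vector when `pred` is given.
#' @param pred Optional predicted class vector.
#' @return Numeric kappa.
#' @export
cohen_kappa <- function(truth, pred = NULL) {
  if (is.null(pred)) {
    cm <- as.matrix(truth)
  } else {
    lev <- sort(unique(c(as.character(truth), as.character(pred))))
    cm <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  }
  if (length(cm) == 0 || sum(cm) == 0) stopf("empty confusion matrix")
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann--Whitney) AUC with midrank tie handling for binary
#' truth. For a multi-class factor truth with a score matrix (one column per
#' class), returns the unweighted mean of the one-vs-rest AUCs.
#'
#' @param scores Numeric score vector, or matrix with one column per class.
#' @param truth Binary 0/1 vector, or factor for the multi-class case.
#' @return AUC in \[0, 1\]; NA when only one class is present.
#' @export
auc_score <- function(scores, truth) {
  if (is.matrix(scores) || is.data.frame(scores)) {
    scores <- as.matrix(scores)
    lev <- colnames(scores) %||% levels(factor(truth))
    per_class <- vapply(lev, function(cl) {
      auc_score(scores[, cl], as.integer(as.character(truth) == cl))
    }, numeric(1))
    return(mean(per_class, na.rm = TRUE))
  }
  stopifnot(length(scores) == length(truth))
  if (length(scores) == 0) stopf("empty input")
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (as.numeric(length(pos)) * length(neg))
}

#' Macro-average of per-label metric values
#'
#' The unweighted arithmetic mean over labels; NA entries (e.g. AUC
#' undefined on a single-class label) are excluded.
#'
#' @param per_label_values Numeric vector of per-label metric values.
#' @return Numeric mean.
#' @export
macro_average <- function(per_label_values) {
  if (length(per_label_values) == 0) stopf("empty input")
  mean(per_label_values, na.rm = TRUE)
}

#' Exact-match (subset) accuracy of a multi-label prediction
#'
#' Fraction of compounds whose entire predicted label tuple matches the
#' truth; stricter than macro-averaged per-label accuracy.
#'
#' @param truth,pred Binary label matrices of identical shape.
#' @return Numeric accuracy.
#' @export
subset_accuracy <- function(truth, pred) {
  stopifnot(all(dim(truth) == dim(pred)))
  mean(apply(truth == pred, 1, all))
}
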