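## Classification metrics: confusion matrices, accuracy, Cohen's kappa,
## threshold-swept ROC curves and one-vs-rest AUC.

#' Confusion-matrix counts
#'
#' @param truth,pred integer labels in \code{0..K-1}.
#' @param K number of classes (default: inferred).
#' @return \code{K x K} count matrix, rows = truth, columns = predicted.
#' @export
confusionCounts <- function(truth, pred, K = max(truth, pred) + 1L) {
  cm <- matrix(0L, K, K, dimnames = list(truth = 0:(K - 1), pred = 0:(K - 1)))
  for (j in seq_along(truth)) cm[truth[j] + 1L, pred[j] + 1L] <-
      cm[truth[j] + 1L, pred[j] + 1L] + 1L
  cm
}

#' Accuracy from a confusion matrix
#'
#' @param cm square count matrix (rows truth, columns predicted).
#' @return percentage, \code{100 * trace / total}.
#' @export
accuracyFromConfusion <- function(cm) {
  total <- sum(cm)
  if (total == 0) .stopf("empty confusion matrix")
  100 * sum(diag(cm)) / total
}

#' Cohen's kappa
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' the expected agreement from the marginal products,
#' \eqn{p_e = \sum_k r_k c_k / N^2}. When \eqn{p_e = 1} (all mass in a
#' single cell) kappa is undefined and returned as 0 with attribute
#' \code{degenerate = TRUE}.
#'
#' @param cm square count matrix.
#' @return kappa in \code{[-1, 1]}.
#' @export
cohenKappa <- function(cm) {
  N <- sum(cm)
  if (N == 0) .stopf("empty confusion matrix")
  po <- sum(diag(cm)) / N
  pe <- sum(rowSums(cm) * colSums(cm)) / N^2
  if (abs(1 - pe) < 1e-12) return(structure(0, degenerate = TRUE))
  (po - pe) / (1 - pe)
}

#' Threshold-swept ROC curve and AUC for one binary contrast
#'
#' Sweeps the distinct score values as thresholds, accumulating the
#' true-positive rate \code{TP/(TP+FN)} against the false-positive rate
#' \code{FP/(FP+TN)}; the area is the trapezoidal integral, which with
#' tie-grouped thresholds equals the Mann-Whitney statistic
#' \eqn{P(s^+ > s^-) + \frac{1}{2} P(s^+ = s^-)}.
#'
#' @param scores numeric scores (higher = more positive).
#' @param positive logical (or 0/1) positive-class indicator.
#' @return list with \code{points} (data.frame fpr, tpr, threshold)
#'   and \code{auc}.
#' @export
rocCurve <- function(scores, positive) {
  positive <- as.logical(positive)
  nP <- sum(positive); nN <- sum(!positive)
  if (nP == 0 || nN == 0)
    .stopf("ROC needs at least one positive and one negative sample")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(t) sum(scores == t & positive), numeric(1)))
  fp <- cumsum(vapply(thr, function(t) sum(scores == t & !positive), numeric(1)))
  tpr <- c(0, tp / nP); fpr <- c(0, fp / nN)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr,
                           threshold = c(Inf, thr)), auc = auc)
}

#' One-vs-rest ROC analysis
#'
#' @param scores \code{N x K} class-score (probability) matrix.
#' @param labels integer labels in \code{0..K-1}.
#' @return list: \code{per_class} (ROC + AUC per class, \code{NULL}
#'   with a flag for degenerate classes) and \code{macro_auc} (mean
#'   over defined classes).
#' @export
rocAuc <- function(scores, labels) {
  K <- ncol(scores)
  per <- vector("list", K)
  aucs <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    pos <- labels == (k - 1L)
    if (!any(pos) || all(pos)) {
      per[[k]] <- list(skipped = TRUE)
      next
    }
    per[[k]] <- rocCurve(scores[, k], pos)
    aucs[k] <- per[[k]]$auc
  }
  list(per_class = per, auc = aucs, macro_auc = mean(aucs, na.rm = TRUE))
}
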