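#' Area under the ROC curve from scores
#'
#' Rank-based (Mann-Whitney) AUROC with midranks for ties; invariant to
#' monotone transforms of the scores.
#'
#' @param scores numeric vector of predicted scores (higher = more positive).
#' @param y binary 0/1 outcome vector.
#' @return AUC in \[0, 1\]; `NA` if only one outcome class is present.
#' @export
aucFromScores <- function(scores, y) {
  y <- as.integer(y)
  nPos <- sum(y == 1L)
  nNeg <- sum(y == 0L)
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Weighted F1 score for multi-class predictions
#'
#' Per-class F1 averaged with weights equal to the true class support
#' (classes absent from the truth get zero weight; an undefined per-class F1
#' counts as 0).
#'
#' @param pred integer vector of predicted class indices.
#' @param truth integer vector of true class indices.
#' @param K number of classes (default: max index observed).
#' @return weighted F1 in \[0, 1\].
#' @export
weightedF1 <- function(pred, truth, K = max(c(pred, truth))) {
  stopifnot(length(pred) == length(truth))
  f1 <- numeric(K)
  support <- numeric(K)
  for (k in seq_len(K)) {
    tp <- sum(pred == k & truth == k)
    fp <- sum(pred == k & truth != k)
    fn <- sum(pred != k & truth == k)
    support[k] <- tp + fn
    f1[k] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  if (sum(support) == 0) return(NA_real_)
  sum(f1 * support) / sum(support)
}

#' Macro one-vs-rest AUROC for class probability matrices
#'
#' One-vs-rest AUROC per class, averaged over classes for which both positives
#' and negatives exist; classes without positives (or negatives) are excluded
#' with a warning.
#'
#' @param probs m x K probability matrix.
#' @param truth integer vector of true class indices (1-based).
#' @return macro-averaged AUROC.
#' @export
macroAUROC <- function(probs, truth) {
  K <- ncol(probs)
  aucs <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    yk <- as.integer(truth == k)
    aucs[k] <- aucFromScores(probs[, k], yk)
  }
  if (anyNA(aucs)) {
    warning(sprintf(
      "AUROC undefined for %d class(es) without both outcomes; excluded",
      sum(is.na(aucs))
    ))
  }
  mean(aucs, na.rm = TRUE)
}

#' Node-classification metric report
#'
#' Computes macro one-vs-rest AUROC and weighted F1. With lists of probability
#' matrices and label vectors (one per slide), metrics are computed per slide
#' and then averaged across slides.
#'
#' @param probs m x K probability matrix, or a list of them.
#' @param labels integer label vector, or a list matching `probs`.
#' @return list with `auroc`, `weightedF1`, and (for multiple slides)
#'   `perSlide`.
#' @export
evaluateNodes <- function(probs, labels) {
  if (is.list(probs) && !is.data.frame(probs)) {
    stopifnot(length(probs) == length(labels))
    per <- data.frame(
      auroc = vapply(seq_along(probs), function(i) macroAUROC(probs[[i]], labels[[i]]), 0),
      weightedF1 = vapply(
        seq_along(probs),
        function(i) {
          weightedF1(max.col(probs[[i]], ties.method = "first"), labels[[i]], K = ncol(probs[[i]]))
        }, 0
      )
    )
    return(list(
      auroc = mean(per$auroc), weightedF1 = mean(per$weightedF1), perSlide = per
    ))
  }
  list(
    auroc = macroAUROC(probs, labels),
    weightedF1 = weightedF1(max.col(probs, ties.method = "first"), labels, K = ncol(probs))
  )
}
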