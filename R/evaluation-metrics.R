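## Performance metrics, with sensitivity and "specificity" exactly as used
## by the validation protocol:
##
##     sens = TP / (TP + FN)         (recall)
##     spec = TP / (TP + FP)         (the positive-predictive form, i.e.
##                                    precision; kept under the name
##                                    'specificity' because the reported
##                                    harmonic mean -- the F1 measure --
##                                    is defined on this pair)
##
## 0/0 ratios are defined as 0.

#' Confusion counts
#'
#' @param predicted,truth +1/-1 label vectors of equal length.
#' @return named list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusionCounts <- function(predicted, truth) {
  pdAssert(length(predicted) == length(truth), "pdValueError",
           "predicted and truth lengths differ")
  pdAssert(all(predicted %in% c(-1L, 1L)) && all(truth %in% c(-1L, 1L)),
           "pdValueError", "labels must be +1/-1")
  list(TP = sum(predicted == 1L & truth == 1L),
       FP = sum(predicted == 1L & truth == -1L),
       TN = sum(predicted == -1L & truth == -1L),
       FN = sum(predicted == -1L & truth == 1L))
}

.safeDiv <- function(num, den) if (den == 0) 0 else num / den

#' Harmonic mean of sensitivity and specificity (F1)
#'
#' @param sens,spec numeric values in \[0, 1\].
#' @return `2 * sens * spec / (sens + spec)`, 0 when both are 0.
#' @export
#' @examples
#' harmonicMean(0.913, 0.875)
harmonicMean <- function(sens, spec) {
  ifelse(sens + spec > 0, 2 * sens * spec / (sens + spec), 0)
}

#' Point metrics from confusion counts
#'
#' @param counts as returned by [confusionCounts()].
#' @return named list: `sensitivity`, `specificity` (= precision, see
#'   above; also exposed under the alias `precision`), `harmonic_mean`,
#'   `sens_times_spec`, `classification_error`.
#' @export
metricSet <- function(counts) {
  sens <- .safeDiv(counts$TP, counts$TP + counts$FN)
  spec <- .safeDiv(counts$TP, counts$TP + counts$FP)
  n <- counts$TP + counts$FP + counts$TN + counts$FN
  list(sensitivity = sens,
       specificity = spec,
       precision = spec,
       harmonic_mean = harmonicMean(sens, spec),
       sens_times_spec = sens * spec,
       classification_error = .safeDiv(counts$FP + counts$FN, n))
}

## Threshold sweep over distinct score values (ties grouped). Returns
## cumulative TP/FP at each distinct threshold, descending.
.sweep <- function(scores, truth) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  t <- truth[o]
  last <- cumsum(rle(s)$lengths)
  list(tp = cumsum(t == 1L)[last], fp = cumsum(t == -1L)[last],
       nPos = sum(truth == 1L), nNeg = sum(truth == -1L))
}

#' Curve metrics: aucROC and aucPRC
#'
#' aucROC is computed by trapezoidal integration of the ROC curve over all
#' distinct score thresholds (tied scores grouped); aucPRC is the area
#' under the step-wise (non-interpolated) precision-recall curve,
#' `sum_k (R_k - R_{k-1}) P_k`. Both are `NA` when only one class is
#' present.
#'
#' @param scores real prediction scores.
#' @param truth +1/-1 labels.
#' @return list with `auc_roc` and `auc_prc`.
#' @export
curveMetrics <- function(scores, truth) {
  pdAssert(length(scores) == length(truth), "pdValueError",
           "scores and truth lengths differ")
  sw <- .sweep(scores, truth)
  if (sw$nPos == 0L || sw$nNeg == 0L) {
    return(list(auc_roc = NA_real_, auc_prc = NA_real_))
  }
  tpr <- c(0, sw$tp / sw$nPos)
  fpr <- c(0, sw$fp / sw$nNeg)
  aucROC <- sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1]) / 2)
  prec <- sw$tp / (sw$tp + sw$fp)
  rec <- sw$tp / sw$nPos
  aucPRC <- sum(diff(c(0, rec)) * prec)
  list(auc_roc = aucROC, auc_prc = aucPRC)
}

#' The regularization grid
#'
#' @return `10^m` for m = -5, ..., 5 (11 log-spaced values).
#' @export
lambdaGrid <- function() 10^(-5:5)
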