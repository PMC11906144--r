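#' Classification metrics from a confusion table
#'
#' Accuracy, precision, recall and F-measure from TP/TN/FP/FN counts:
#' accuracy = (TP+TN)/(TP+FP+FN+TN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F = 2PR/(P+R). A ratio with a zero denominator
#' is returned as 0 and flagged in `$undefined`, so pooled tables never
#' propagate NaN silently.
#'
#' @param TP,TN,FP,FN non-negative integer counts; their sum must be
#'   positive.
#' @return list with `accuracy`, `precision`, `recall`, `f_measure`,
#'   plus auxiliary `specificity` and `balanced_accuracy` (mean of
#'   recall and specificity, used for method selection on imbalanced
#'   targets), and a character vector `undefined` naming any
#'   zero-denominator metrics.
#' @examples
#' classificationMetrics(TP = 2, FP = 1, FN = 1, TN = 6)
#' @export
classificationMetrics <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (sum(counts) == 0) stop("confusion counts are all zero")
  undefined <- character()
  safe <- function(num, den, what) {
    if (den == 0) { undefined <<- c(undefined, what); 0 } else num / den
  }
  precision <- safe(TP, TP + FP, "precision")
  recall <- safe(TP, TP + FN, "recall")
  f <- safe(2 * precision * recall, precision + recall, "f_measure")
  specificity <- safe(TN, TN + FP, "specificity")
  list(accuracy = (TP + TN) / sum(counts),
       precision = precision, recall = recall, f_measure = f,
       specificity = specificity,
       balanced_accuracy = (recall + specificity) / 2,
       undefined = undefined)
}

#' Confusion counts from observed/predicted labels
#'
#' @param observed,predicted vectors of class labels.
#' @param positive the label treated as the positive class.
#' @return list of TP/TN/FP/FN counts.
#' @export
confusionCounts <- function(observed, predicted, positive = "positive") {
  stopifnot(length(observed) == length(predicted))
  obs <- observed == positive; pred <- predicted == positive
  list(TP = sum(obs & pred), TN = sum(!obs & !pred),
       FP = sum(!obs & pred), FN = sum(obs & !pred))
}

#' Regression metrics
#'
#' r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
#' MAE = mean(|y - yhat|), RMSE = sqrt(mean((y - yhat)^2)).
#' r2 is undefined (returned as NA, flagged) when the observed vector is
#' constant; MAE and RMSE are still returned.
#'
#' @param observed,predicted numeric vectors of equal length (n >= 2).
#' @return list with `r2`, `mae`, `rmse` and `undefined`.
#' @examples
#' regressionMetrics(c(0, 2), c(1, 1))   # MAE 1, RMSE 1, r2 0
#' @export
regressionMetrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (length(observed) < 2) stop("at least two samples are required")
  if (anyNA(observed) || anyNA(predicted)) stop("NA in inputs")
  resid2 <- sum((observed - predicted)^2)
  tot2 <- sum((observed - mean(observed))^2)
  undefined <- character()
  r2 <- if (tot2 == 0) { undefined <- "r2"; NA_real_ } else 1 - resid2 / tot2
  list(r2 = r2,
       mae = sum(abs(observed - predicted)) / length(observed),
       rmse = sqrt(resid2 / length(observed)),
       undefined = undefined)
}
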