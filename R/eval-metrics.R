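#' Confusion counts for a binary task
#'
#' Tallies TP/FP/TN/FN with class 1 (abnormal) as the positive class. The
#' four counts partition the samples.
#'
#' @param y_true,y_pred binary vectors of equal length (`>= 1`).
#' @return A `confusion_counts` list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (length(y_true) < 1L) stop("need at least one sample", call. = FALSE)
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels and predictions must be binary (0/1)", call. = FALSE)
  }
  structure(list(
    TP = sum(y_true == 1 & y_pred == 1),
    FP = sum(y_true == 0 & y_pred == 1),
    TN = sum(y_true == 0 & y_pred == 0),
    FN = sum(y_true == 1 & y_pred == 0)
  ), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' * accuracy    = (TP + TN) / (TP + FP + TN + FN)
#' * precision   = TP / (TP + FP)
#' * recall      = sensitivity = TP / (TP + FN)
#' * specificity = TN / (TN + FP)
#' * f1          = harmonic mean of precision and recall
#'
#' Any metric whose denominator is zero is returned as `NA_real_` (the
#' undefined marker) rather than silently as 0, so seed-averaged tables can
#' distinguish "no positives predicted" from "perfectly wrong".
#'
#' @param counts a [confusion()] result.
#' @return A `metrics_bundle` list with `accuracy`, `precision`, `recall`,
#'   `f1`, `sensitivity`, `specificity` (each in \[0, 1\] or `NA`).
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total < 1L) stop("empty confusion counts", call. = FALSE)

  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(TP, TP + FP)
  recall <- safe_div(TP, TP + FN)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(
    accuracy = (TP + TN) / total,
    precision = precision,
    recall = recall,
    f1 = f1,
    sensitivity = recall,
    specificity = safe_div(TN, TN + FP)
  ), class = "metrics_bundle")
}
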