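#' Binary classification metrics for one validation fold
#'
#' Computes accuracy, sensitivity (true-positive rate), specificity
#' (true-negative rate), balanced accuracy (their mean), and the ROC AUC.
#' The AUC is the probability that a randomly chosen positive receives a
#' higher confidence than a randomly chosen negative, with ties counting
#' one half — computed via the exact Mann-Whitney rank formula, which is
#' algebraically identical to brute-force enumeration of all
#' positive-negative pairs.
#'
#' @param true_labels binary 0/1 vector.
#' @param confidences numeric vector in `[0, 1]`, same length.
#' @param threshold decision threshold (see [classify()]).
#' @return Object of class `msi_metrics`: a list with `accuracy`,
#'   `balanced_accuracy`, `sensitivity`, `specificity`, `auc`, and counts
#'   `tp`, `fp`, `tn`, `fn`. `auc` is `NA` when only one class is present
#'   (with a warning).
#' @export
compute_metrics <- function(true_labels, confidences, threshold = 0.5) {
  stopifnot(length(true_labels) == length(confidences))
  y <- as.integer(true_labels)
  stopifnot(all(y %in% c(0L, 1L)))
  pred <- classify(confidences, threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  np <- sum(y == 1L); nn <- sum(y == 0L)
  sens <- if (np > 0) tp / np else NA_real_
  spec <- if (nn > 0) tn / nn else NA_real_
  auc <- if (np > 0 && nn > 0) {
    r <- rank(confidences, ties.method = "average")
    (sum(r[y == 1L]) - np * (np + 1) / 2) / (np * nn)
  } else {
    warning("AUC undefined: only one class present")
    NA_real_
  }
  structure(
    list(accuracy = (tp + tn) / length(y),
         balanced_accuracy = (sens + spec) / 2,
         sensitivity = sens, specificity = spec, auc = auc,
         tp = tp, fp = fp, tn = tn, fn = fn),
    class = "msi_metrics")
}

#' @export
print.msi_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("accuracy %.4f | balanced %.4f | sensitivity %.4f | ",
           "specificity %.4f | AUC %s\n"),
    x$accuracy, x$balanced_accuracy, x$sensitivity, x$specificity,
    ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc))))
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Fuse a tissue group's spectrum confidences into one decision
#'
#' The per-sample decision rule: the median of all raw per-spectrum
#' confidences of the group (for an even count, the mean of the two middle
#' values) is thresholded by the standard rule — median below the threshold
#' is negative, at or above is positive.
#'
#' @param confidences numeric vector of per-spectrum confidences, length
#'   at least 1.
#' @param threshold decision threshold.
#' @return List with `median_confidence` and `predicted` (0/1).
#' @export
fuse_group <- function(confidences, threshold = 0.5) {
  if (length(confidences) == 0L) stop("cannot fuse an empty tissue group")
  med <- stats::median(confidences)
  list(median_confidence = med,
       predicted = classify(med, threshold))
}
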