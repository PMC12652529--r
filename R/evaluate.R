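# Performance metrics: multiclass confusion matrices, binary counts and
# derived metrics for a designated positive class (BrdU by default), and the
# area under the precision-recall curve.

#' Multiclass confusion matrix over the five base classes
#'
#' @param truth,calls Character vectors of equal length with symbols from
#'   `classes` (B = BrdU). Rows of the result are truth, columns prediction.
#' @param classes Class universe, in fixed order (default A, B, C, G, T).
#' @return Integer matrix of class `brdu_confusion`.
#' @examples
#' brdu_confusion(c("T", "T", "B"), c("T", "B", "B"))
#' @export
brdu_confusion <- function(truth, calls, classes = CLASS_NAMES) {
  if (length(truth) != length(calls))
    stop("truth and calls must have equal length", call. = FALSE)
  bad <- setdiff(unique(c(truth, calls)), classes)
  if (length(bad))
    stop(sprintf("unknown class symbol(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  cm <- table(factor(truth, levels = classes), factor(calls, levels = classes))
  m <- matrix(as.integer(cm), length(classes), length(classes),
              dimnames = list(truth = classes, predicted = classes))
  structure(m, class = c("brdu_confusion", "matrix"))
}

#' @export
print.brdu_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = truth, columns = prediction; B = BrdU)\n")
  print(unclass(x))
  invisible(x)
}

#' Collapse a confusion matrix to binary counts for one positive class
#'
#' @param cm A [brdu_confusion()] matrix.
#' @param positive Positive class symbol (default `"B"`, BrdU).
#' @return List with `TP`, `TN`, `FP`, `FN`.
#' @export
collapse_binary <- function(cm, positive = "B") {
  stopifnot(positive %in% rownames(cm))
  tp <- cm[positive, positive]
  fn <- sum(cm[positive, ]) - tp
  fp <- sum(cm[, positive]) - tp
  tn <- sum(cm) - tp - fn - fp
  list(TP = as.integer(tp), TN = as.integer(tn), FP = as.integer(fp),
       FN = as.integer(fn))
}

#' Binary classification metrics from TP/TN/FP/FN counts
#'
#' Computes accuracy `(TP + TN) / (TP + TN + FP + FN)`, precision
#' `TP / (TP + FP)`, sensitivity (= recall) `TP / (TP + FN)` and specificity
#' `TN / (TN + FP)`. A metric whose denominator is zero is reported as `NA`
#' (undefined), never coerced to 0.
#'
#' @param TP,TN,FP,FN Non-negative counts, or pass a list from
#'   [collapse_binary()] as `TP`.
#' @return Named numeric vector `accuracy`, `precision`, `sensitivity`,
#'   `specificity`.
#' @examples
#' binary_metrics(TP = 90, TN = 95, FP = 5, FN = 10)
#' @export
binary_metrics <- function(TP, TN = NULL, FP = NULL, FN = NULL) {
  if (is.list(TP)) { cnt <- TP; TP <- cnt$TP; TN <- cnt$TN; FP <- cnt$FP; FN <- cnt$FN }
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  c(accuracy = ratio(TP + TN, TP + TN + FP + FN),
    precision = ratio(TP, TP + FP),
    sensitivity = ratio(TP, TP + FN),
    specificity = ratio(TN, TN + FP))
}

#' Aggregated multiclass accuracy, precision and recall
#'
#' Accuracy is the trace over the total. Precision and recall are one-vs-rest
#' per class and then averaged, support-weighted by default (each class
#' weighted by its number of true instances) or unweighted (`"macro"`).
#' Classes with an undefined per-class value (zero support, or never
#' predicted) contribute 0 to the average, as standard toolkits report.
#'
#' @param cm A [brdu_confusion()] matrix.
#' @param average `"weighted"` (default) or `"macro"`.
#' @return Named numeric vector `accuracy`, `precision`, `recall`.
#' @export
multiclass_summary <- function(cm, average = c("weighted", "macro")) {
  average <- match.arg(average)
  total <- sum(cm)
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  diagv <- diag(unclass(cm))
  support <- rowSums(cm)
  predicted <- colSums(cm)
  prec_i <- ifelse(predicted > 0, diagv / predicted, 0)
  rec_i <- ifelse(support > 0, diagv / support, 0)
  if (average == "weighted") {
    wts <- support / total
  } else {
    present <- support > 0
    wts <- as.numeric(present) / sum(present)
  }
  c(accuracy = sum(diagv) / total,
    precision = sum(wts * prec_i),
    recall = sum(wts * rec_i))
}

#' Area under the precision-recall curve (average precision)
#'
#' Uses the average-precision formulation: the sum over distinct score
#' thresholds of precision times the recall increment (step-wise, no linear
#' interpolation between operating points), which avoids the optimistic bias
#' of trapezoidal interpolation. The positive class is BrdU in this
#' package's evaluations.
#'
#' @param scores Numeric scores for the positive class (higher = more
#'   positive), e.g. the `p_BrdU` column of a calls table.
#' @param truth Logical (or 0/1) vector: is the instance truly positive?
#' @return Area in `[0, 1]`.
#' @examples
#' auprc(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE))  # 1
#' @export
auprc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth))
    stop("scores and truth must have equal length", call. = FALSE)
  n_pos <- sum(truth)
  if (n_pos == 0L || n_pos == length(truth))
    stop("need at least one positive and one negative instance", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  cum_tp <- cumsum(t)
  cum_n <- seq_along(t)
  # operating points: last index of each tied score block
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  precision <- cum_tp[last] / cum_n[last]
  recall <- cum_tp[last] / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Evaluate a calls table against known truth
#'
#' Convenience wrapper assembling the full metric set: the 5-class confusion
#' matrix, its BrdU-vs-rest binary collapse with binary metrics, the
#' aggregated multiclass summary, and the area under the BrdU
#' precision-recall curve (when both classes are present).
#'
#' @param calls Calls `data.frame` from [predict.brdu_bigru()].
#' @param truth Character vector of true center bases (A/B/C/G/T), aligned
#'   with `calls` rows.
#' @param positive Positive class (default `"B"`).
#' @param average Aggregation for [multiclass_summary()].
#' @return List with `confusion`, `binary_counts`, `binary`, `multiclass`,
#'   `auprc` and `n`.
#' @export
evaluate_calls <- function(calls, truth, positive = "B",
                           average = c("weighted", "macro")) {
  cm <- brdu_confusion(truth, calls$call)
  counts <- collapse_binary(cm, positive)
  is_pos <- truth == positive
  pr <- if (any(is_pos) && !all(is_pos)) auprc(calls$p_BrdU, is_pos) else NA_real_
  list(confusion = cm, binary_counts = counts, binary = binary_metrics(counts),
       multiclass = multiclass_summary(cm, match.arg(average)),
       auprc = pr, n = nrow(calls))
}
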