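#' Confusion counts for nuclear/cytosolic predictions
#'
#' The positive class is `nuclear`: TP = predicted and truly nuclear,
#' TN = predicted and truly cytosolic, FP = predicted nuclear but truly
#' cytosolic, FN = predicted cytosolic but truly nuclear.
#'
#' @param pred,truth Equal-length vectors (factor or character) over
#'   \{"nuclear", "cytosolic"\}.
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion <- function(pred, truth) {
  pred <- as.character(pred); truth <- as.character(truth)
  if (length(pred) != length(truth)) stop("pred and truth length mismatch")
  ok <- c("nuclear", "cytosolic")
  if (!all(pred %in% ok) || !all(truth %in% ok)) {
    stop("labels must be 'nuclear' or 'cytosolic'")
  }
  c(TP = sum(pred == "nuclear" & truth == "nuclear"),
    TN = sum(pred == "cytosolic" & truth == "cytosolic"),
    FP = sum(pred == "nuclear" & truth == "cytosolic"),
    FN = sum(pred == "cytosolic" & truth == "nuclear"))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall on the nuclear class), specificity, F1
#' (harmonic mean of precision and recall) and the Matthews correlation
#' coefficient. Degenerate denominators follow the standard conventions:
#' a metric whose denominator is zero is `NaN` (sensitivity with no true
#' positives-plus-false-negatives, specificity with no negatives, F1 with
#' zero precision-plus-recall), except MCC, which is defined as 0 whenever
#' any factor of its denominator vanishes.
#'
#' @param counts Named vector with `TP`, `TN`, `FP`, `FN` (from
#'   [confusion()]), total >= 1.
#' @return List of class `metrics_report`: `counts`, `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `f1`, `mcc`.
#' @examples
#' metrics(c(TP = 50, TN = 50, FP = 0, FN = 0))$mcc  # 1
#' @export
metrics <- function(counts) {
  stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(counts)))
  tp <- as.numeric(counts[["TP"]]); tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]]); fn <- as.numeric(counts[["FN"]])
  total <- tp + tn + fp + fn
  if (total < 1) stop("empty confusion counts")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NaN
  spec <- if (tn + fp > 0) tn / (tn + fp) else NaN
  prec <- if (tp + fp > 0) tp / (tp + fp) else NaN
  f1 <- if (is.finite(prec) && is.finite(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NaN
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 > 0) (tp * tn - fp * fn) / sqrt(denom2) else 0
  structure(list(counts = c(TP = tp, TN = tn, FP = fp, FN = fn),
                 accuracy = (tp + tn) / total, sensitivity = sens,
                 specificity = spec, precision = prec, f1 = f1, mcc = mcc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Classification metrics (positive class: nuclear)\n")
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d\n", x$counts[["TP"]],
              x$counts[["TN"]], x$counts[["FP"]], x$counts[["FN"]]))
  for (m in c("accuracy", "sensitivity", "specificity", "f1", "mcc")) {
    cat(sprintf("  %-12s %.4f\n", m, x[[m]]))
  }
  if (!is.null(x$auc)) cat(sprintf("  %-12s %.4f\n", "auc", x$auc))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision cutoff over all distinct scores to trace the ROC
#' curve and integrates it by the trapezoidal rule. Tied scores are handled
#' as a single operating-point jump, which makes the trapezoidal area equal
#' to the Mann-Whitney concordance probability (ties get half credit).
#'
#' @param scores Numeric vector of nuclear-class scores, higher = more
#'   nuclear.
#' @param truth Labels over \{"nuclear", "cytosolic"\}, aligned with
#'   `scores`; both classes must be present.
#' @return List with `roc` (data frame `cutoff`, `fpr`, `tpr`, starting at
#'   (0,0) and ending at (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.character(truth)
  stopifnot(length(scores) == length(truth),
            all(truth %in% c("nuclear", "cytosolic")))
  pos <- truth == "nuclear"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs at least one positive and one negative")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # collapse tied scores into single operating points
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- cumsum(p)[last_of_tie] / n_pos
  fpr <- cumsum(!p)[last_of_tie] / n_neg
  roc <- data.frame(cutoff = c(Inf, s[last_of_tie]),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(roc = roc, auc = auc)
}

#' Full evaluation of predicted probabilities against truth
#'
#' Convenience wrapper: hard labels at the given cutoff, confusion counts,
#' the scalar metrics and the ROC/AUC in one report.
#'
#' @param proba Probability matrix with a `P_nuclear` column (from
#'   [predict.dnn_localizer()]) or numeric vector of nuclear probabilities.
#' @param truth Labels over \{"nuclear", "cytosolic"\}.
#' @param cutoff Classification cutoff (default 0.5).
#' @return `metrics_report` with `auc` and `roc` fields added.
#' @export
evaluate_predictions <- function(proba, truth, cutoff = 0.5) {
  p_nuc <- if (is.matrix(proba)) proba[, "P_nuclear"] else proba
  rep <- metrics(confusion(classify(p_nuc, cutoff), truth))
  ra <- roc_auc(p_nuc, truth)
  rep$auc <- ra$auc
  rep$roc <- ra$roc
  rep
}
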