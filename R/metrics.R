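#' Classification metrics from confusion counts
#'
#' Computes accuracy, precision, recall and F1 from the four confusion
#' counts.  The default orientation is the standard one
#' (precision = TP/(TP+FP), recall = TP/(TP+FN)).  `orientation =
#' "swapped"` exchanges the two denominators (precision = TP/(TP+FN)),
#' a convention occasionally seen in print; it is provided for
#' comparison only.
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @param orientation `"standard"` (default) or `"swapped"`.
#' @return List with the four counts and `accuracy`, `precision`,
#'   `recall`, `f1` (fractions; `NaN` where a denominator is zero).
#' @examples
#' classification_metrics(tp = 3, fp = 1, tn = 4, fn = 2)
#' @export
classification_metrics <- function(tp, fp, tn, fn,
                                   orientation = c("standard", "swapped")) {
  orientation <- match.arg(orientation)
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion table", call. = FALSE)
  precision <- if (orientation == "standard") tp / (tp + fp) else tp / (tp + fn)
  recall <- if (orientation == "standard") tp / (tp + fn) else tp / (tp + fp)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / total,
       precision = precision,
       recall = recall,
       f1 = 2 * tp / (2 * tp + fp + fn))
}

#' Area under the ROC curve by the rank statistic
#'
#' Wilcoxon/Mann-Whitney formulation with midrank tie handling: the
#' probability that a randomly chosen active scores above a randomly
#' chosen inactive, ties counting one half.
#'
#' @param truth Logical vector (`TRUE` = active) or character with
#'   values `"active"`/`"inactive"`.
#' @param score Numeric predicted scores/probabilities.
#' @return AUC in `[0, 1]`; `NA` if only one class is present.
#' @export
auc_rank <- function(truth, score) {
  if (is.character(truth) || is.factor(truth)) truth <- as.character(truth) == "active"
  stopifnot(is.logical(truth), length(truth) == length(score))
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# assemble a metrics_report from truth + probabilities at a threshold
.metrics_report <- function(truth, prob, threshold = 0.5,
                            orientation = "standard") {
  pred <- prob >= threshold
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  m <- classification_metrics(tp, fp, tn, fn, orientation = orientation)
  m$auc <- auc_rank(truth, prob)
  m$n <- length(truth)
  structure(m, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> n =", x$n, "\n")
  cat(sprintf("  accuracy %.3f  precision %.3f  recall %.3f  f1 %.3f  auc %s\n",
              x$accuracy, x$precision, x$recall, x$f1,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}
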