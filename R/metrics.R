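#' Evaluation metrics for imbalanced binary classification
#'
#' Melanoma is the positive class throughout. Besides the standard
#' confusion-table metrics (accuracy, sensitivity, specificity, precision,
#' F-score, Matthews correlation), the imbalance-aware family is provided:
#' the geometric mean of sensitivity and specificity, the dominance
#' (sensitivity minus specificity), and the index of balanced accuracy
#' `IBA = (1 - dominance) * G-mean^2`. AUC is computed from continuous
#' scores by the rank (Mann-Whitney) statistic; balanced accuracy is
#' reported alongside it.
#'
#' @name metrics-module
NULL

#' Confusion counts for binary labels
#'
#' @param y_true,y_pred equal-length binary label vectors
#'   (1 = melanoma = positive).
#' @return object of class `confusion_counts`: list with `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("label lengths differ")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) stop("labels must be 0/1")
  out <- list(tp = sum(y_true == 1 & y_pred == 1),
              tn = sum(y_true == 0 & y_pred == 0),
              fp = sum(y_true == 0 & y_pred == 1),
              fn = sum(y_true == 1 & y_pred == 0))
  class(out) <- "confusion_counts"
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: tp=%d tn=%d fp=%d fn=%d\n", x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (zero denominator); reported as NaN", what))
    return(NaN)
  }
  num / den
}

#' Confusion-table metrics
#'
#' Accuracy, sensitivity (recall), specificity, precision,
#' F-score `2tp / (2tp + fp + fn)`, Matthews correlation coefficient, and
#' balanced accuracy. Ratios with zero denominators are reported as NaN
#' with a warning.
#'
#' @param c a [confusion()] object.
#' @return named list of class `metrics_report` (without AUC and the
#'   imbalance family; see [metrics_report()] for the full suite).
#' @export
classification_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  n <- c$tp + c$tn + c$fp + c$fn
  if (n == 0) stop("empty confusion table")
  sens <- safe_ratio(c$tp, c$tp + c$fn, "sensitivity")
  spec <- safe_ratio(c$tn, c$tn + c$fp, "specificity")
  mcc_den <- sqrt(as.double(c$tp + c$fp)) * sqrt(as.double(c$tp + c$fn)) *
             sqrt(as.double(c$tn + c$fp)) * sqrt(as.double(c$tn + c$fn))
  mcc <- if (mcc_den == 0) {
    warning("MCC undefined (zero denominator); reported as NaN")
    NaN
  } else (as.double(c$tp) * c$tn - as.double(c$fp) * c$fn) / mcc_den
  list(accuracy = (c$tp + c$tn) / n,
       sensitivity = sens,
       specificity = spec,
       precision = safe_ratio(c$tp, c$tp + c$fp, "precision"),
       f_score = safe_ratio(2 * c$tp, 2 * c$tp + c$fp + c$fn, "F-score"),
       mcc = mcc,
       balanced_accuracy = (sens + spec) / 2)
}

#' Imbalance-aware metric family
#'
#' `g_mean = sqrt(sensitivity * specificity)`,
#' `dominance = sensitivity - specificity`,
#' `iba = (1 - dominance) * g_mean^2`.
#'
#' @param sensitivity,specificity rates in \[0, 1\].
#' @return list with `g_mean`, `dominance`, `iba`.
#' @export
imbalance_metrics <- function(sensitivity, specificity) {
  for (v in c(sensitivity, specificity))
    if (is.na(v) || v < 0 || v > 1) stop("rates must lie in [0, 1]")
  g <- sqrt(sensitivity * specificity)
  d <- sensitivity - specificity
  list(g_mean = g, dominance = d, iba = (1 - d) * g^2)
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney statistic of the continuous scores: the probability that a
#' random positive scores above a random negative, ties counting one half.
#'
#' @param scores numeric scores, higher = more melanoma-like.
#' @param y_true binary labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, y_true) {
  if (length(scores) != length(y_true)) stop("lengths differ")
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full evaluation report
#'
#' Combines the confusion-table metrics, the imbalance family, and (when
#' scores are supplied) the rank-based AUC.
#'
#' @param y_true,y_pred binary label vectors.
#' @param scores optional continuous scores for AUC.
#' @return object of class `metrics_report`.
#' @export
metrics_report <- function(y_true, y_pred, scores = NULL) {
  cc <- confusion(y_true, y_pred)
  m <- classification_metrics(cc)
  im <- imbalance_metrics(m$sensitivity, m$specificity)
  m <- c(m, im)
  m$auc <- if (!is.null(scores)) auc_score(scores, y_true) else NA_real_
  m$confusion <- cc
  class(m) <- "metrics_report"
  m
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Evaluation report (positive class = melanoma)\n")
  print(x$confusion)
  fields <- c("accuracy", "sensitivity", "specificity", "precision",
              "f_score", "mcc", "balanced_accuracy", "auc",
              "g_mean", "dominance", "iba")
  for (f in fields)
    cat(sprintf("  %-18s %s\n", f,
                ifelse(is.na(x[[f]]), "NA", sprintf("%.4f", x[[f]]))))
  invisible(x)
}
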