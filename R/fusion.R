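#' Mutual-information feature fusion
#'
#' After handcrafted and deep features are concatenated, each column's
#' mutual information (MI) with the binary class label is estimated and the
#' arithmetic mean of the per-feature MI values is used as a threshold:
#' only features scoring strictly above the mean survive. MI for continuous
#' columns uses the Ross k-nearest-neighbor estimator for mixed
#' discrete-continuous data (Chebyshev distance, digamma correction); a
#' plug-in binned estimator is available as an alternative.
#'
#' @name fusion-module
NULL

#' Labelled feature matrix
#'
#' The tabular unit of the fusion, balancing, and classification stages.
#'
#' @param X n x p numeric matrix, no missing values.
#' @param y length-n binary labels (0 = nevus/benign, 1 = melanoma).
#' @param feature_names optional p feature names (default from columns).
#' @param provenance optional per-row flag, `"real"` or `"synthetic"`
#'   (SMOTE-generated rows).
#' @return object of class `feature_matrix`: list with `X`, `y`,
#'   `feature_names`, `provenance`.
#' @export
feature_matrix <- function(X, y, feature_names = NULL, provenance = NULL) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stop("X must be finite with no NAs")
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (is.null(feature_names))
    feature_names <- if (!is.null(colnames(X))) colnames(X)
                     else sprintf("f%d", seq_len(ncol(X)))
  if (length(feature_names) != ncol(X))
    stop("feature_names length must equal ncol(X)")
  colnames(X) <- feature_names
  if (is.null(provenance)) provenance <- rep("real", nrow(X))
  out <- list(X = X, y = y, feature_names = feature_names,
              provenance = provenance)
  class(out) <- "feature_matrix"
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d instances x %d features (%d positive, %d negative)\n",
              nrow(x$X), ncol(x$X), sum(x$y == 1), sum(x$y == 0)))
  invisible(x)
}

# Deterministic tie-breaking jitter: duplicated values would create zero
# k-NN distances, which the estimator cannot use. The jitter scale is tied
# to the data spread and the stream seed makes it reproducible per column.
jitter_ties <- function(x, seed) {
  if (!anyDuplicated(x)) return(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  with_local_seed(seed, x + rnorm(length(x), sd = 1e-10 * s))
}

#' k-nearest-neighbor mutual information with a discrete label
#'
#' Ross's estimator for the MI between a continuous variable and a discrete
#' label: for each point, the Chebyshev distance to its k-th nearest
#' neighbor *within its own label class* defines a radius; `m` counts all
#' points (any label) strictly inside that radius, and the estimate averages
#' `digamma(N) - digamma(N_y) + digamma(k) - digamma(m)`. Negative raw
#' estimates are clamped to zero. Duplicate values are broken by a
#' deterministic jitter at 1e-10 of the data spread.
#'
#' @param x numeric vector.
#' @param y binary labels of the same length; each class must have more
#'   than `k` members.
#' @param k neighbor count (default 3).
#' @param jitter_seed seed for the deterministic tie-breaking jitter.
#' @return nonnegative MI estimate in nats.
#' @export
mi_knn <- function(x, y, k = 3L, jitter_seed = 1L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L * k + 2L) stop("need at least 2k + 2 observations")
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both label classes must be present")
  if (min(table(y)) <= k)
    stop("a label class has <= k members; lower k")
  x <- jitter_ties(as.numeric(x), jitter_seed)
  max(0, .mi_knn_cpp(x, y, as.integer(k)))
}

#' Binned (plug-in) mutual information
#'
#' Discretizes `x` into `bins` equal-width bins and computes the plug-in
#' discrete MI against the label, in nats.
#'
#' @param x numeric vector.
#' @param y labels of the same length.
#' @param bins number of equal-width bins (>= 2).
#' @return nonnegative MI estimate in nats.
#' @export
mi_binned <- function(x, y, bins = 16L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (bins < 2L) stop("bins must be >= 2")
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  b <- pmin(pmax(floor((x - rng[1]) / (rng[2] - rng[1]) * bins) + 1L, 1L),
            as.integer(bins))
  joint <- table(b, y) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  terms <- joint * log(joint / outer(px, py))
  terms[joint == 0] <- 0
  max(0, sum(terms))
}

#' Per-feature MI scores against the class label
#'
#' Applies [mi_knn()] independently to every column of a
#' [feature_matrix()].
#'
#' @param data a `feature_matrix`.
#' @param k neighbor count passed to [mi_knn()].
#' @param estimator `"knn"` (default) or `"binned"`.
#' @param bins bin count for the binned estimator.
#' @return object of class `mi_scores`: list with `scores` (named,
#'   nonnegative), `k`, `estimator`.
#' @export
mi_scores <- function(data, k = 3L, estimator = c("knn", "binned"),
                      bins = 16L) {
  stopifnot(inherits(data, "feature_matrix"))
  estimator <- match.arg(estimator)
  p <- ncol(data$X)
  scores <- numeric(p)
  for (j in seq_len(p)) {
    scores[j] <- tryCatch(
      if (estimator == "knn")
        mi_knn(data$X[, j], data$y, k = k, jitter_seed = j)
      else mi_binned(data$X[, j], data$y, bins = bins),
      error = function(e)
        stop(sprintf("MI estimation failed for feature '%s': %s",
                     data$feature_names[j], conditionMessage(e)),
             call. = FALSE))
  }
  names(scores) <- data$feature_names
  out <- list(scores = scores, k = as.integer(k), estimator = estimator)
  class(out) <- "mi_scores"
  out
}

#' @export
print.mi_scores <- function(x, ...) {
  cat(sprintf("mi_scores (%s estimator, k = %d): %d features, mean MI %.4g nats\n",
              x$estimator, x$k, length(x$scores), mean(x$scores)))
  invisible(x)
}

#' Mean-threshold feature selection
#'
#' Keeps the features whose MI score is strictly greater than the
#' arithmetic mean of all scores. If no feature qualifies (all scores
#' equal), the single highest-scoring feature (lowest index on ties) is
#' kept so the selection is never empty.
#'
#' @param scores an [mi_scores()] object.
#' @return object of class `selection_mask`: list with logical `keep`,
#'   numeric `threshold`, and the `scores`.
#' @export
select_features <- function(scores) {
  stopifnot(inherits(scores, "mi_scores"))
  s <- scores$scores
  thr <- mean(s)
  keep <- s > thr
  if (!any(keep)) keep[which.max(s)] <- TRUE
  out <- list(keep = keep, threshold = thr, scores = s)
  class(out) <- "selection_mask"
  out
}

#' @export
print.selection_mask <- function(x, ...) {
  cat(sprintf("selection_mask: kept %d of %d features (mean-MI threshold %.4g nats)\n",
              sum(x$keep), length(x$keep), x$threshold))
  invisible(x)
}
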