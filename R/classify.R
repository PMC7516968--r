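#' Shallow classifiers on fused features
#'
#' After fusion and balancing, a shallow classifier separates melanoma from
#' nevus: logistic regression, a support vector machine with linear or RBF
#' kernel, or (optionally, when the kernlab backend is installed) a
#' relevance vector machine run in regression mode on +/-1 labels.
#'
#' @name classify-module
NULL

classifier_kinds <- c("logistic", "svm_linear", "svm_rbf", "rvm")

#' Train a shallow classifier
#'
#' @param data a [feature_matrix()] with >= 2 instances per class.
#' @param kind one of `"logistic"`, `"svm_linear"`, `"svm_rbf"`, `"rvm"`.
#' @param hyper named list of hyperparameters: `C` (SVM cost, default 1),
#'   `gamma` (RBF width, default `1/ncol(X)`).
#' @param seed integer seed (used by stochastic backends; fits here are
#'   deterministic given data and seed).
#' @return object of class `lesion_classifier` providing hard labels and
#'   continuous scores through [predict()].
#' @export
train_classifier <- function(data, kind = "svm_rbf", hyper = list(),
                             seed = 1L) {
  stopifnot(inherits(data, "feature_matrix"))
  if (!kind %in% classifier_kinds)
    stop("unknown classifier kind '", kind, "'; available: ",
         paste(classifier_kinds, collapse = ", "))
  if (min(table(data$y)) < 2L) stop("need at least 2 instances per class")
  X <- data$X; y <- data$y
  C <- if (!is.null(hyper$C)) hyper$C else 1
  gamma <- if (!is.null(hyper$gamma)) hyper$gamma else 1 / ncol(X)
  flip <- 1
  threshold <- 0
  if (kind == "logistic") {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, X), y, family = stats::binomial()))
    fit <- fit$coefficients
    fit[!is.finite(fit)] <- 0
    threshold <- 0.5
  } else if (kind %in% c("svm_linear", "svm_rbf")) {
    fit <- e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                      kernel = if (kind == "svm_linear") "linear" else "radial",
                      cost = C, gamma = gamma, scale = FALSE)
    dv <- attr(stats::predict(fit, X, decision.values = TRUE),
               "decision.values")[, 1]
    # orient decision values so larger = more melanoma-like
    if (mean(dv[y == 1]) < mean(dv[y == 0])) flip <- -1
  } else {  # rvm
    if (!requireNamespace("kernlab", quietly = TRUE))
      stop("classifier kind 'rvm' requires the kernlab backend, ",
           "which is not installed")
    fit <- with_local_seed(seed, suppressWarnings(
      kernlab::rvm(x = X, y = 2 * y - 1, kernel = "rbfdot",
                   kpar = list(sigma = gamma))))
  }
  out <- list(kind = kind, fit = fit, flip = flip, threshold = threshold,
              n_features = ncol(X), feature_names = data$feature_names,
              hyper = list(C = C, gamma = gamma), seed = as.integer(seed))
  class(out) <- "lesion_classifier"
  out
}

#' @export
print.lesion_classifier <- function(x, ...) {
  cat(sprintf("lesion_classifier: %s on %d features (threshold %.3g)\n",
              x$kind, x$n_features, x$threshold))
  invisible(x)
}

#' Predict labels and scores from a trained classifier
#'
#' @param object a `lesion_classifier`.
#' @param newdata numeric matrix or [feature_matrix()] with the training
#'   feature count.
#' @param ... unused.
#' @return list with integer `labels` (score >= threshold) and numeric
#'   `scores` monotone in melanoma confidence.
#' @export
predict.lesion_classifier <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$X
       else as.matrix(newdata)
  if (ncol(X) != object$n_features)
    stop(sprintf("newdata has %d features, model was trained on %d",
                 ncol(X), object$n_features))
  scores <- switch(object$kind,
    logistic = as.vector(stats::plogis(cbind(1, X) %*% object$fit)),
    svm_linear = ,
    svm_rbf = object$flip *
      attr(stats::predict(object$fit, X, decision.values = TRUE),
           "decision.values")[, 1],
    rvm = as.vector(kernlab::predict(object$fit, X)))
  list(labels = as.integer(scores >= object$threshold),
       scores = as.numeric(scores))
}
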