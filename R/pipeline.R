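#' Fit the full melanoma/nevus CAD pipeline
#'
#' `cad_fit()` runs the end-to-end pipeline on labelled dermoscopy images:
#' segmentation and ROI extraction, the 43-element handcrafted descriptor,
#' deep features through the configured extractor, fusion by concatenation,
#' a stratified train/test split, z-score normalization fitted on the
#' training partition, mutual-information scoring and mean-MI feature
#' selection on the training partition, SMOTE balancing of the training
#' partition, classifier training, and evaluation on the untouched test
#' partition. All statistics that could leak information (normalization,
#' MI, SMOTE) are fitted on the training partition only; every source of
#' randomness derives from the single `seed`, so a rerun with the same
#' inputs reproduces the fit exactly.
#'
#' @param images list of H x W x 3 RGB arrays (values in \[0, 255\]), at
#'   least 4.
#' @param labels binary vector (1 = melanoma), both classes present.
#' @param sigma Gaussian blur standard deviation for segmentation.
#' @param extractor a [feature_extractor()]; default is a
#'   [surrogate_extractor()] with 32 filters seeded from `seed`.
#' @param lesion_only compute color/texture over lesion pixels only.
#' @param glcm_levels,glcm_distance GLCM quantization and offset distance.
#' @param mi_k neighbor count for the MI estimator.
#' @param smote_k SMOTE neighbor pool size.
#' @param train_fraction training fraction of the stratified split.
#' @param classifier classifier kind (see [train_classifier()]).
#' @param hyper classifier hyperparameters.
#' @param seed master seed; named substreams are derived for the split,
#'   SMOTE, the surrogate extractor, and classifier training.
#' @return object of class `cad_fit` with components `config`, `extractor`,
#'   `scaler` (normalization statistics), `mi` ([mi_scores()]),
#'   `selection` ([select_features()] mask), `classifier`, `report`
#'   (stage counts plus the test-partition [metrics_report()]), and the
#'   test-set predictions.
#' @examples
#' \donttest{
#' corpus <- lapply(1:8, function(i) {
#'   dark <- i %% 2 == 1
#'   make_lesion_image(synthetic_lesion_spec(
#'     image_size = c(96, 128), n_colors = if (dark) 3 else 1,
#'     seed = i))$image
#' })
#' fit <- cad_fit(corpus, labels = rep(c(1, 0), 4), seed = 7,
#'                extractor = surrogate_extractor(7, dim = 8))
#' print(fit)
#' }
#' @export
cad_fit <- function(images, labels, sigma = 3, extractor = NULL,
                    lesion_only = TRUE, glcm_levels = 32L,
                    glcm_distance = 1L, mi_k = 3L, smote_k = 5L,
                    train_fraction = 0.75, classifier = "svm_rbf",
                    hyper = list(), seed = 1L) {
  if (!is.list(images) || length(images) < 4L)
    stop("need a list of at least 4 images")
  labels <- as.integer(labels)
  if (length(labels) != length(images)) stop("one label per image required")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (is.null(extractor))
    extractor <- surrogate_extractor(derive_seed(seed, "surrogate"),
                                     dim = 32L)
  config <- list(sigma = sigma, extractor = extractor$name,
                 extractor_dim = extractor$dim, lesion_only = lesion_only,
                 glcm_levels = glcm_levels, glcm_distance = glcm_distance,
                 mi_k = mi_k, smote_k = smote_k,
                 train_fraction = train_fraction, classifier = classifier,
                 seed = as.integer(seed))

  feats <- vapply(seq_along(images), function(i) {
    roi <- tryCatch(preprocess(images[[i]], sigma = sigma),
                    error = function(e)
                      stop(sprintf("preprocess failed for image %d: %s",
                                   i, conditionMessage(e)), call. = FALSE))
    hand <- handcraft_vector(roi, lesion_only = lesion_only,
                             n_levels = glcm_levels,
                             distance = glcm_distance)
    concat_features(extract_deep(roi, extractor), hand)
  }, numeric(extractor$dim + 43L))
  full <- feature_matrix(t(feats), labels)

  parts <- split_data(full, train_fraction = train_fraction,
                      seed = derive_seed(seed, "split"))
  sc <- zscore_fit_apply(parts$train, parts$test)

  # cap the neighbor count at what the training partition supports;
  # degenerate partitions fall back to the binned estimator
  k_eff <- min(mi_k, min(table(sc$train$y)) - 1L,
               (nrow(sc$train$X) - 2L) %/% 2L)
  mi <- if (k_eff >= 1L) mi_scores(sc$train, k = k_eff)
        else mi_scores(sc$train, estimator = "binned")
  sel <- select_features(mi)
  subset_fm <- function(fm) feature_matrix(fm$X[, sel$keep, drop = FALSE],
                                           fm$y,
                                           fm$feature_names[sel$keep],
                                           fm$provenance)
  train_sel <- subset_fm(sc$train)
  test_sel <- subset_fm(sc$test)

  counts_before <- table(factor(train_sel$y, levels = c(0L, 1L)))
  train_bal <- smote(train_sel, k_neighbors = smote_k,
                     seed = derive_seed(seed, "smote"))
  counts_after <- table(factor(train_bal$y, levels = c(0L, 1L)))

  model <- train_classifier(train_bal, kind = classifier, hyper = hyper,
                            seed = derive_seed(seed, "train"))
  pred <- stats::predict(model, test_sel)
  report <- list(
    config = config,
    n_images = length(images),
    n_features_total = ncol(full$X),
    n_features_selected = sum(sel$keep),
    n_train = nrow(parts$train$X), n_test = nrow(parts$test$X),
    train_class_counts = as.integer(counts_before),
    train_class_counts_balanced = as.integer(counts_after),
    metrics = metrics_report(test_sel$y, pred$labels, pred$scores),
    timestamp = format(Sys.time(), tz = "UTC"))

  out <- list(config = config, extractor = extractor, scaler = sc[c("center", "scale")],
              mi = mi, selection = sel, classifier = model,
              feature_names = full$feature_names, report = report,
              test_predictions = pred, test_labels = test_sel$y)
  class(out) <- "cad_fit"
  out
}

#' @export
print.cad_fit <- function(x, ...) {
  r <- x$report
  cat("CAD pipeline fit (melanoma vs nevus)\n")
  cat(sprintf("  images: %d (train %d / test %d), extractor %s (dim %d)\n",
              r$n_images, r$n_train, r$n_test, x$config$extractor,
              x$config$extractor_dim))
  cat(sprintf("  features: %d fused -> %d selected (mean-MI threshold %.4g)\n",
              r$n_features_total, r$n_features_selected,
              x$selection$threshold))
  cat(sprintf("  train class counts 0/1: %d/%d -> %d/%d after SMOTE\n",
              r$train_class_counts[1], r$train_class_counts[2],
              r$train_class_counts_balanced[1],
              r$train_class_counts_balanced[2]))
  cat(sprintf("  test accuracy %.3f, IBA %.3f\n",
              r$metrics$accuracy, r$metrics$iba))
  invisible(x)
}

#' @export
summary.cad_fit <- function(object, ...) {
  print(object)
  cat("\nTest-partition metrics:\n")
  print(object$report$metrics)
  kept <- names(object$selection$scores)[object$selection$keep]
  cat(sprintf("\nTop selected features (of %d):\n", length(kept)))
  top <- sort(object$selection$scores[object$selection$keep],
              decreasing = TRUE)
  print(round(head(top, 10), 4))
  invisible(object)
}

#' Predict melanoma probability/labels for new images
#'
#' Applies the fitted preprocessing, feature extraction, normalization,
#' and feature selection to new images and scores them with the trained
#' classifier.
#'
#' @param object a `cad_fit`.
#' @param images list of RGB arrays.
#' @param ... unused.
#' @return list with `labels` and `scores`.
#' @export
predict.cad_fit <- function(object, images, ...) {
  if (!is.list(images)) images <- list(images)
  cfg <- object$config
  feats <- vapply(images, function(img) {
    roi <- preprocess(img, sigma = cfg$sigma)
    hand <- handcraft_vector(roi, lesion_only = cfg$lesion_only,
                             n_levels = cfg$glcm_levels,
                             distance = cfg$glcm_distance)
    concat_features(extract_deep(roi, object$extractor), hand)
  }, numeric(cfg$extractor_dim + 43L))
  X <- t(feats)
  X <- sweep(sweep(X, 2, object$scaler$center, "-"), 2,
             object$scaler$scale, "/")
  stats::predict(object$classifier, X[, object$selection$keep, drop = FALSE])
}

#' Plot MI scores and the selection threshold of a fit
#'
#' Bar plot of the per-feature mutual-information scores with the mean-MI
#' selection threshold; selected features are shaded.
#'
#' @param x a `cad_fit`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.cad_fit <- function(x, ...) {
  s <- x$selection$scores
  graphics::barplot(s, border = NA, names.arg = rep("", length(s)),
                    col = ifelse(x$selection$keep, "firebrick", "grey70"),
                    ylab = "MI with label (nats)", xlab = "feature index",
                    ...)
  graphics::abline(h = x$selection$threshold, lty = 2)
  invisible(x)
}
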