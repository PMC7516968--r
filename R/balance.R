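#' Class balancing and normalization
#'
#' Training data are balanced by SMOTE: synthetic minority points are
#' interpolated between a minority instance and one of its k nearest
#' minority neighbors (Euclidean distance) until both classes have equal
#' counts. Features are z-score normalized with statistics fitted on the
#' training partition only.
#'
#' @name balance-module
NULL

#' SMOTE oversampling of the minority class
#'
#' Each synthetic point is `x_i + u * (x_nn - x_i)` with `u ~ U(0, 1)` and
#' `x_nn` one of the `k_neighbors` nearest minority-class neighbors of the
#' minority point `x_i` (base points are cycled so generation is spread
#' evenly). Synthetic rows carry provenance `"synthetic"`; classes are
#' exactly equal afterwards.
#'
#' @param data a [feature_matrix()]; minority class must have >= 2 rows.
#' @param k_neighbors neighbor pool size (default 5, capped at the
#'   minority size minus one).
#' @param seed integer seed; output is deterministic given the seed.
#' @return a [feature_matrix()] with equal class counts.
#' @export
smote <- function(data, k_neighbors = 5L, seed = 1L) {
  stopifnot(inherits(data, "feature_matrix"))
  tab <- table(factor(data$y, levels = c(0L, 1L)))
  if (tab[1] == tab[2]) return(data)
  min_lab <- as.integer(names(tab)[which.min(tab)])
  n_min <- min(tab); n_syn <- max(tab) - n_min
  if (n_min < 2L) stop("minority class must have at least 2 members")
  idx_min <- which(data$y == min_lab)
  Xm <- data$X[idx_min, , drop = FALSE]
  k <- min(as.integer(k_neighbors), n_min - 1L)
  if (k < 1L) stop("k_neighbors must be >= 1")
  d2 <- as.matrix(stats::dist(Xm))^2
  diag(d2) <- Inf
  nn <- matrix(0L, n_min, k)
  for (i in seq_len(n_min)) nn[i, ] <- order(d2[i, ])[seq_len(k)]
  syn <- with_local_seed(seed, {
    base <- rep_len(seq_len(n_min), n_syn)
    pick <- nn[cbind(base, sample.int(k, n_syn, replace = TRUE))]
    u <- runif(n_syn)
    Xm[base, , drop = FALSE] +
      u * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
  })
  feature_matrix(rbind(data$X, syn),
                 c(data$y, rep(min_lab, n_syn)),
                 data$feature_names,
                 c(data$provenance, rep("synthetic", n_syn)))
}

#' Fit z-score normalization on train, apply to train and test
#'
#' Per-column mean and (sample) standard deviation are estimated on the
#' training partition only and applied to both partitions. Zero-variance
#' columns pass through unscaled with a warning.
#'
#' @param train a [feature_matrix()].
#' @param test optional [feature_matrix()] transformed with the training
#'   statistics.
#' @return list with transformed `train`, `test` (or NULL), and the
#'   fitted `center` and `scale` vectors.
#' @export
zscore_fit_apply <- function(train, test = NULL) {
  stopifnot(inherits(train, "feature_matrix"))
  if (nrow(train$X) == 0L) stop("training partition is empty")
  center <- colMeans(train$X)
  scale <- apply(train$X, 2, stats::sd)
  zero <- !is.finite(scale) | scale == 0
  if (any(zero)) {
    warning(sprintf("%d constant column(s) passed through unscaled: %s",
                    sum(zero),
                    paste(head(train$feature_names[zero], 5), collapse = ", ")))
    scale[zero] <- 1
    center[zero] <- 0
  }
  tr <- function(fm) {
    X <- sweep(sweep(fm$X, 2, center, "-"), 2, scale, "/")
    feature_matrix(X, fm$y, fm$feature_names, fm$provenance)
  }
  list(train = tr(train), test = if (!is.null(test)) tr(test),
       center = center, scale = scale)
}

#' Stratified train/test split
#'
#' Randomly partitions rows, preserving class proportions (per-class
#' rounding of `train_fraction`). Deterministic given the seed.
#'
#' @param data a [feature_matrix()].
#' @param train_fraction fraction of rows in the training partition.
#' @param seed integer seed.
#' @return list with `train`, `test` ([feature_matrix()]s) and the row
#'   indices `train_idx`, `test_idx`.
#' @export
split_data <- function(data, train_fraction = 0.75, seed = 1L) {
  stopifnot(inherits(data, "feature_matrix"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  classes <- sort(unique(data$y))
  n_cl <- vapply(classes, function(cl) sum(data$y == cl), numeric(1))
  # per-class counts: floors, then distribute the remainder against the
  # overall round(fraction * n) target by largest fractional part
  base <- floor(train_fraction * n_cl)
  rem <- round(train_fraction * nrow(data$X)) - sum(base)
  if (rem > 0) {
    ord <- order(train_fraction * n_cl - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  train_idx <- with_local_seed(seed, {
    unlist(lapply(seq_along(classes), function(ci) {
      idx <- which(data$y == classes[ci])
      sample(idx)[seq_len(base[ci])]
    }))
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(nrow(data$X)), train_idx)
  sub <- function(idx) feature_matrix(data$X[idx, , drop = FALSE],
                                      data$y[idx], data$feature_names,
                                      data$provenance[idx])
  tr <- sub(train_idx); te <- sub(test_idx)
  if (length(unique(tr$y)) < 2L || length(unique(te$y)) < 2L)
    stop("a class is absent from one partition; adjust train_fraction or n")
  list(train = tr, test = te, train_idx = train_idx, test_idx = test_idx)
}
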