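test_that("confusion tallies the 2x2 table", {
  cc <- confusion(rep(1L, 8), rep(1L, 8))
  expect_equal(c(cc$tp, cc$tn, cc$fp, cc$fn), c(8, 0, 0, 0))
  cc <- confusion(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(c(cc$tp, cc$tn), c(0, 0))
  set.seed(60)
  yt <- rbinom(20, 1, .5); yp <- rbinom(20, 1, .5)
  cc <- confusion(yt, yp)
  expect_equal(cc$tp, sum(yt & yp))
  expect_equal(cc$fn, sum(yt & !yp))
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 20)
  expect_error(confusion(1:3 > 1, c(TRUE, FALSE)), "lengths")
})

test_that("classification_metrics reproduce the defining formulas", {
  perfect <- confusion(rep(c(1L, 0L), each = 50), rep(c(1L, 0L), each = 50))
  m <- classification_metrics(perfect)
  expect_equal(m$accuracy, 1); expect_equal(m$mcc, 1)
  expect_equal(m$f_score, 1)

  # uniform table: no better than chance
  uni <- structure(list(tp = 25, tn = 25, fp = 25, fn = 25),
                   class = "confusion_counts")
  m <- classification_metrics(uni)
  expect_equal(m$mcc, 0); expect_equal(m$accuracy, 0.5)

  # harmonic-mean identity f = 2PR/(P+R) on random tables
  set.seed(70)
  for (rep in 1:20) {
    cc <- structure(as.list(setNames(sample(1:40, 4, replace = TRUE),
                                     c("tp", "tn", "fp", "fn"))),
                    class = "confusion_counts")
    m <- classification_metrics(cc)
    expect_equal(m$f_score,
                 2 * m$precision * m$sensitivity /
                   (m$precision + m$sensitivity),
                 tolerance = 1e-12)
    expect_gte(m$mcc, -1); expect_lte(m$mcc, 1)
    # MCC is symmetric under simultaneous class relabelling
    sw <- structure(list(tp = cc$tn, tn = cc$tp, fp = cc$fn, fn = cc$fp),
                    class = "confusion_counts")
    expect_equal(classification_metrics(sw)$mcc, m$mcc, tolerance = 1e-12)
  }
  expect_error(classification_metrics(
    structure(list(tp = 0, tn = 0, fp = 0, fn = 0),
              class = "confusion_counts")), "empty")
})

test_that("imbalance metrics follow their defining identities", {
  im <- imbalance_metrics(0.9, 0.9)
  expect_equal(im$g_mean, 0.9)
  expect_equal(im$dominance, 0)
  expect_equal(im$iba, 0.81)
  im <- imbalance_metrics(1, 0)
  expect_equal(im$g_mean, 0); expect_equal(im$iba, 0)
  im <- imbalance_metrics(0.8641, 0.90)
  expect_equal(im$g_mean, sqrt(0.8641 * 0.90), tolerance = 1e-12)
  expect_equal(im$g_mean, 0.8819, tolerance = 1e-4)
  expect_equal(im$iba, (1 - (0.8641 - 0.90)) * 0.8641 * 0.90,
               tolerance = 1e-12)
  expect_equal(im$iba, 0.8056, tolerance = 1e-4)
  expect_error(imbalance_metrics(1.2, 0.5), "rates")
})

test_that("auc_score is the Mann-Whitney statistic", {
  y <- c(0, 0, 0, 1, 1, 1)
  expect_equal(auc_score(c(1, 2, 3, 7, 8, 9), y), 1)
  expect_equal(auc_score(rep(5, 6), y), 0.5)
  # exhaustive pair counting on a toy list with a tie across classes
  s <- c(0.1, 0.4, 0.35, 0.8, 0.4, 0.9)
  pairs <- expand.grid(p = which(y == 1), n = which(y == 0))
  want <- mean(ifelse(s[pairs$p] > s[pairs$n], 1,
                      ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
  expect_equal(auc_score(s, y), want)
  # invariance under strictly monotone transforms
  set.seed(80)
  sc <- rnorm(60); yy <- rbinom(60, 1, .5)
  expect_equal(auc_score(sc, yy), auc_score(exp(sc), yy))
  # independent cross-check against pROC
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(auc_score(sc, yy),
                 as.numeric(pROC::auc(pROC::roc(yy, sc, quiet = TRUE,
                                                direction = "<"))))
  }
  expect_error(auc_score(sc, rep(1, 60)), "classes")
})

test_that("metrics_report combines the full suite coherently", {
  set.seed(81)
  yt <- rbinom(40, 1, .5); sc <- rnorm(40) + yt
  yp <- as.integer(sc > 0.5)
  r <- metrics_report(yt, yp, sc)
  expect_equal(r$g_mean, sqrt(r$sensitivity * r$specificity))
  expect_equal(r$iba, (1 - r$dominance) * r$g_mean^2)
  expect_equal(r$balanced_accuracy, (r$sensitivity + r$specificity) / 2)
  expect_equal(r$auc, auc_score(sc, yt))
})

test_that("classifiers separate separable data deterministically", {
  set.seed(90)
  X <- rbind(matrix(rnorm(40, mean = 0, sd = .4), 20, 2),
             matrix(rnorm(40, mean = 3, sd = .4), 20, 2))
  y <- rep(c(0L, 1L), each = 20)
  fm <- feature_matrix(X, y)
  for (kind in c("logistic", "svm_linear", "svm_rbf")) {
    mod <- train_classifier(fm, kind = kind, seed = 2)
    pr <- predict(mod, X)
    expect_equal(pr$labels, y, info = kind)
    expect_identical(pr, predict(train_classifier(fm, kind = kind, seed = 2), X))
    expect_equal(pr$labels, as.integer(pr$scores >= mod$threshold))
  }
  expect_error(train_classifier(fm, kind = "forest"), "unknown")
  mod <- train_classifier(fm, "svm_rbf")
  expect_error(predict(mod, X[, 1, drop = FALSE]), "features")
})

test_that("the RBF kernel beats the linear kernel on concentric circles", {
  set.seed(91)
  n <- 120
  r <- c(runif(n / 2, 0, 1), runif(n / 2, 2, 3))
  th <- runif(n, 0, 2 * pi)
  X <- cbind(r * cos(th), r * sin(th))
  y <- rep(c(0L, 1L), each = n / 2)
  idx <- sample(n, 80)
  tr <- feature_matrix(X[idx, ], y[idx])
  te_X <- X[-idx, ]; te_y <- y[-idx]
  acc <- function(kind) {
    mod <- train_classifier(tr, kind = kind, seed = 3)
    mean(predict(mod, te_X)$labels == te_y)
  }
  expect_gt(acc("svm_rbf"), acc("svm_linear"))
  expect_gte(acc("svm_rbf"), 0.9)
})

test_that("the optional relevance vector machine backend works when present", {
  skip_if_not_installed("kernlab")
  set.seed(92)
  X <- rbind(matrix(rnorm(40, 0, .4), 20, 2), matrix(rnorm(40, 3, .4), 20, 2))
  fm <- feature_matrix(X, rep(c(0L, 1L), each = 20))
  mod <- train_classifier(fm, kind = "rvm", seed = 4)
  expect_equal(predict(mod, X)$labels, fm$y)
})
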