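test_that("gaussian_blur preserves constants, matches the kernel, and smooths", {
  img <- array(128, c(20, 20, 3))
  expect_equal(gaussian_blur(img, 2), img, tolerance = 1e-10)

  # single bright pixel: center of the response equals the kernel peak
  sigma <- 1
  img <- array(0, c(21, 21, 3)); img[11, 11, ] <- 255
  half <- ceiling(3 * sigma)
  xs <- -half:half
  k <- outer(xs, xs, function(x, y) exp(-(x^2 + y^2) / (2 * sigma^2)))
  k <- k / sum(k)
  out <- gaussian_blur(img, sigma)
  expect_equal(out[11, 11, 1], 255 * k[half + 1, half + 1], tolerance = 1e-6)

  set.seed(4)
  img <- array(runif(24 * 24 * 3, 0, 255), c(24, 24, 3))
  out <- gaussian_blur(img, 2)
  for (ch in 1:3) expect_lt(var(as.vector(out[, , ch])),
                            var(as.vector(img[, , ch])))
  expect_error(gaussian_blur(img, 0), "sigma")
  expect_error(gaussian_blur(img, -1), "sigma")
})

test_that("rgb_to_lab matches the sRGB/D65 reference transform", {
  mk <- function(val) array(rep(val, each = 16 * 16), c(16, 16, 3))
  white <- rgb_to_lab(mk(c(255, 255, 255)))
  expect_equal(white$L[1, 1], 100, tolerance = 1e-6)
  expect_equal(white$a[1, 1], 0, tolerance = 1e-6)
  expect_equal(white$b[1, 1], 0, tolerance = 1e-6)
  black <- rgb_to_lab(mk(c(0, 0, 0)))
  expect_equal(black$L[1, 1], 0, tolerance = 1e-8)
  # mid-gray: L from the standard transform, frozen reference value
  gray <- rgb_to_lab(mk(c(119, 119, 119)))
  expect_equal(gray$L[1, 1], 50.034, tolerance = 1e-3)
  expect_equal(gray$a[1, 1], 0, tolerance = 1e-6)
  expect_equal(gray$b[1, 1], 0, tolerance = 1e-6)
})

test_that("mean_threshold_channel marks values at or above the mean", {
  expect_equal(mean_threshold_channel(matrix(7, 3, 3)), matrix(1L, 3, 3))
  expect_equal(mean_threshold_channel(matrix(c(0, 0, 10, 10), 2, 2)),
               matrix(c(0L, 0L, 1L, 1L), 2, 2))
  set.seed(11)
  ch <- matrix(rnorm(15 * 13), 15, 13)
  expect_equal(mean_threshold_channel(ch), (ch >= mean(ch)) + 0L)
})

test_that("combine_masks is the pixelwise AND", {
  ones <- matrix(1L, 4, 4); zeros <- matrix(0L, 4, 4)
  expect_equal(combine_masks(ones, ones, ones), ones)
  expect_equal(combine_masks(ones, zeros, ones), zeros)
  set.seed(2)
  ms <- replicate(3, matrix(rbinom(36, 1, .5), 6, 6), simplify = FALSE)
  expect_equal(combine_masks(ms[[1]], ms[[2]], ms[[3]]),
               pmin(ms[[1]], ms[[2]], ms[[3]]))
  expect_true(all(combine_masks(ms[[1]], ms[[2]], ms[[3]]) <= ms[[1]]))
  expect_error(combine_masks(ones, matrix(1L, 3, 3), ones), "dimension")
})

test_that("median_filter_mask is the windowed majority vote", {
  ones <- matrix(1L, 10, 10)
  expect_equal(median_filter_mask(ones, 5), ones)
  speck <- matrix(0L, 11, 11); speck[6, 6] <- 1L
  expect_equal(median_filter_mask(speck, 5), matrix(0L, 11, 11))
  # disc with specks: specks removed, disc essentially preserved
  m <- disc_mask(20, 6)
  set.seed(3)
  specks <- m
  flat <- which(specks == 0)
  specks[sample(flat, 5)] <- 1L
  filtered <- median_filter_mask(specks, 5)
  expect_equal(sum(filtered & !m), 0)              # all specks gone
  expect_gt(sum(filtered & m) / sum(m), 0.9)       # disc body kept
  # brute-force window oracle on random masks
  set.seed(9)
  for (rep in 1:3) {
    r <- matrix(rbinom(15 * 12, 1, .5), 15, 12)
    expect_equal(median_filter_mask(r, 3), median_oracle(r, 3))
    expect_equal(median_filter_mask(r, 5), median_oracle(r, 5))
  }
  expect_error(median_filter_mask(ones, 4), "odd")
})

test_that("lesion_mask resolves polarity and picks the interior component", {
  disc <- disc_mask(40, 8)
  expect_equal(lesion_mask(disc, clean_brush = 0), disc)
  # inverted polarity: disc of 0s on a field of 1s
  expect_equal(lesion_mask(1L - disc, clean_brush = 0), disc)
  # default artifact cleaning leaves a blob essentially unchanged
  got <- lesion_mask(disc)
  expect_gt(sum(got & disc) / sum(got | disc), 0.9)
  # two blobs, one touching the border: the interior one wins even if smaller
  two <- disc_mask(60, 9, center = c(30, 30))
  two[1:12, 40:60] <- 1L                            # border-touching block
  got <- suppressWarnings(lesion_mask(two))
  expect_equal(sum(got & disc_mask(60, 9, center = c(30, 30))) / sum(got), 1,
               tolerance = 0.05)
  expect_false(any(got[1, ] == 1))
  expect_error(lesion_mask(matrix(1L, 20, 20)), "uniform")
})

test_that("bounding_box is tight, half-open and 0-based", {
  m <- matrix(0L, 10, 12); m[3:5, 4:8] <- 1L
  bb <- bounding_box(m)
  expect_equal(unclass(bb)[c("row_min", "col_min", "row_max", "col_max")],
               list(row_min = 2L, col_min = 3L, row_max = 5L, col_max = 8L))
  s <- matrix(0L, 5, 5); s[1, 1] <- 1L
  expect_equal(unlist(unclass(bounding_box(s))), c(row_min = 0L, col_min = 0L,
                                                   row_max = 1L, col_max = 1L))
  set.seed(5)
  r <- matrix(rbinom(150, 1, .2), 15, 10)
  bb <- bounding_box(r)
  idx <- which(r == 1, arr.ind = TRUE)
  expect_equal(bb$row_min, min(idx[, 1]) - 1L)
  expect_equal(bb$col_max, max(idx[, 2]))
  expect_error(bounding_box(matrix(0L, 4, 4)), "no lesion")
})

test_that("preprocess recovers the true lesion box on synthetic images", {
  g <- make_lesion_image(synthetic_lesion_spec(image_size = c(300, 400),
                                               seed = 2))
  roi <- preprocess(g$image)
  tb <- bounding_box(g$mask)
  expect_true(all(abs(unlist(unclass(roi$box))[1:4] -
                      unlist(unclass(tb))[1:4]) <= 5))
  expect_true(all(dim(roi$rgb)[1:2] == dim(roi$mask)))
  expect_true(all(dim(roi$lab$L) == dim(roi$mask)))
  expect_gte(sum(roi$mask), 1)
  # uniform image: no lesion to find
  expect_error(preprocess(array(120, c(64, 64, 3))), "uniform|no lesion")
})

test_that("preprocess tolerates hair-like artifacts", {
  g <- make_lesion_image(synthetic_lesion_spec(image_size = c(300, 400),
                                               seed = 7, hair_count = 20))
  roi <- preprocess(g$image)
  tb <- bounding_box(g$mask)
  expect_true(all(abs(unlist(unclass(roi$box))[1:4] -
                      unlist(unclass(tb))[1:4]) <= 15))
})

test_that("preprocess is deterministic and masks overlap ground truth", {
  g <- make_lesion_image(synthetic_lesion_spec(image_size = c(300, 400),
                                               seed = 4))
  r1 <- preprocess(g$image); r2 <- preprocess(g$image)
  expect_identical(r1, r2)
  # IoU property on artifact-free images (lesion/skin L-contrast ~50 units)
  for (s in c(1, 3, 6)) {
    g <- make_lesion_image(synthetic_lesion_spec(image_size = c(300, 400),
                                                 seed = s, hair_count = 0))
    roi <- preprocess(g$image)
    full <- matrix(0L, 300, 400)
    full[(roi$box$row_min + 1):roi$box$row_max,
         (roi$box$col_min + 1):roi$box$col_max] <- roi$mask
    iou <- sum(full & g$mask) / sum(full | g$mask)
    expect_gte(iou, 0.8)
  }
})
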