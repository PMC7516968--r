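test_that("symmetry is 1 for self-coincident shapes and 0 off-axis", {
  expect_equal(symmetry(disc_mask(60, 20)), 1, tolerance = 0.02)
  expect_equal(symmetry(ellipse_mask(120, 160, 50, 25, theta_deg = 25)), 1,
               tolerance = 0.02)
  # lesion entirely on one side of a supplied axis: reflection is disjoint
  m <- matrix(0L, 60, 60); m[3:7, 10:20] <- 1L
  s <- lesionfuse:::symmetry_about_axis(m, 0, c(30, 15))
  expect_equal(s, 0)
})

test_that("symmetry matches the exhaustive pixel oracle on a half-disc", {
  hd <- disc_mask(60, 18, center = c(30, 30))
  hd[, 1:29] <- 0L
  mm <- lesionfuse:::mask_moments(hd)
  for (th in c(mm$theta, mm$theta + pi / 2)) {
    got <- lesionfuse:::symmetry_about_axis(hd, th, mm$center)
    want <- symmetry_axis_oracle(hd, th, mm$center)
    expect_equal(got, want, tolerance = 0.02)
  }
})

test_that("symmetry is invariant to translation and 90-degree rotation", {
  m <- ellipse_mask(100, 140, 35, 18, theta_deg = 40)
  base <- symmetry(m)
  shifted <- matrix(0L, 120, 160)
  shifted[11:110, 15:154] <- m
  expect_equal(symmetry(shifted), base, tolerance = 0.01)
  rotated <- t(m)[ncol(m):1, ]           # 90-degree rotation
  expect_equal(symmetry(rotated), base, tolerance = 0.01)
})

test_that("shape_features reproduce closed-form geometry", {
  sq <- matrix(0L, 14, 14); sq[3:12, 3:12] <- 1L
  expect_equal(shape_features(sq)$area, 100)

  d <- disc_mask(160, 64)
  sf <- shape_features(d)
  expect_gte(sf$circularity, 0.95); expect_lte(sf$circularity, 1.1)
  expect_equal(sf$diameter, 128, tolerance = 0.05 * 128)
  expect_equal(sf$eccentricity, 0, tolerance = 0.05)

  rect <- matrix(0L, 60, 20); rect[11:50, 6:15] <- 1L
  sf <- shape_features(rect)
  expect_equal(sf$eccentricity, sqrt(1 - (10 / 40)^2), tolerance = 0.05)

  line <- matrix(0L, 20, 20); line[10, 3:17] <- 1L
  expect_warning(sfl <- shape_features(line), "degenerate")
  expect_equal(sfl$eccentricity, 1)
  expect_error(shape_features(matrix(0L, 5, 5)), "4 lesion")
})

test_that("the disc maximizes circularity among equal-area ellipses", {
  circ <- vapply(list(c(40, 40), c(50, 32), c(64, 25), c(80, 20)),
                 function(ab) shape_features(
                   ellipse_mask(220, 220, ab[1], ab[2]))$circularity,
                 numeric(1))
  expect_true(all(diff(circ) < 0))
})

test_that("color_features match masked per-channel statistics", {
  rgb <- array(90, c(20, 20, 3))
  mask <- disc_mask(20, 6)
  roi <- make_roi(rgb, mask)
  cf <- color_features(roi)
  expect_length(cf, 24)
  expect_equal(cf[["R_min"]], cf[["R_max"]])
  expect_equal(cf[["G_var"]], 0)

  # two-valued lesion: mean 100, population variance 2500
  rgb2 <- array(0, c(20, 20, 3))
  idx <- which(mask == 1)
  idx <- idx[seq_len(2 * (length(idx) %/% 2))]   # even count
  mask2 <- matrix(0L, 20, 20); mask2[idx] <- 1L
  half <- idx[seq_len(length(idx) / 2)]
  for (ch in 1:3) {
    plane <- matrix(50, 20, 20); plane[half] <- 150
    rgb2[, , ch] <- plane
  }
  cf2 <- color_features(make_roi(rgb2, mask2))
  expect_equal(cf2[["R_mean"]], 100)
  expect_equal(cf2[["R_var"]], 2500)

  # random lesion: brute recomputation over masked pixels, all channels
  set.seed(21)
  rgb3 <- array(runif(20 * 20 * 3, 0, 255), c(20, 20, 3))
  roi3 <- make_roi(rgb3, mask)
  cf3 <- color_features(roi3)
  chans <- list(R = rgb3[, , 1], G = rgb3[, , 2], B = rgb3[, , 3],
                L = roi3$lab$L, a = roi3$lab$a, b = roi3$lab$b)
  for (nm in names(chans)) {
    v <- chans[[nm]][mask == 1]
    expect_equal(cf3[[paste0(nm, "_min")]], min(v))
    expect_equal(cf3[[paste0(nm, "_max")]], max(v))
    expect_equal(cf3[[paste0(nm, "_mean")]], mean(v))
    expect_equal(cf3[[paste0(nm, "_var")]], mean((v - mean(v))^2))
  }
  # whole-crop mode uses every pixel
  cf4 <- color_features(roi3, lesion_only = FALSE)
  expect_equal(cf4[["R_mean"]], mean(rgb3[, , 1]))
})

test_that("handcraft_vector has 43 stable, componentwise-consistent slots", {
  g <- make_lesion_image(synthetic_lesion_spec(image_size = c(160, 200),
                                               seed = 12, n_colors = 3))
  roi <- preprocess(g$image)
  h1 <- handcraft_vector(roi)
  expect_length(h1, 43)
  expect_true(all(is.finite(h1)))
  expect_identical(h1, handcraft_vector(roi))

  sf <- shape_features(roi$mask)
  expect_equal(h1[["symmetry"]], sf$symmetry)
  expect_equal(h1[["area"]], sf$area)
  expect_equal(h1[["circularity"]], sf$circularity)
  expect_equal(h1[7:30], color_features(roi), tolerance = 1e-12)
  gray <- quantize_gray(gray_from_rgb(roi$rgb), 32)
  expect_equal(h1[31:43], texture_features(gray, mask = roi$mask),
               tolerance = 1e-12)
})

test_that("tds_score applies the clinical weights and cutoffs", {
  r <- tds_score(0, 0, 1, 1)
  expect_equal(r$score, 1.0); expect_equal(r$category, "benign")
  r <- tds_score(2, 8, 6, 4)
  expect_equal(r$score, 8.4); expect_equal(r$category, "malignant")
  r <- tds_score(1, 8, 4, 3)
  expect_equal(r$score, 5.6); expect_equal(r$category, "malignant")
  expect_equal(tds_score(2, 8, 2, 1)$category, "suspicious")  # 4.9
  expect_error(tds_score(3, 0, 1, 1), "asymmetry")
  expect_error(tds_score(0, 9, 1, 1), "borders")
  expect_error(tds_score(0, 0, 0, 1), "colors")
  expect_error(tds_score(0, 0, 1, 5), "structures")
})
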