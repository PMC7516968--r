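#' Handcrafted ABCD-style features
#'
#' The 43-element handcrafted descriptor encodes the clinical ABCD
#' attributes with image-processing surrogates: bilateral asymmetry about
#' the principal axes (1), moment-ellipse shape descriptors (5), per-channel
#' color statistics over RGB and CIELab (24), and Haralick co-occurrence
#' texture statistics (13). The classic Total Dermatoscopic Score utility is
#' included for clinically scored inputs.
#'
#' @name handcraft-module
NULL

# Second central moments (per-pixel, area-normalized) of a binary mask in
# x = column, y = row coordinates, plus the principal-axis orientation.
mask_moments <- function(mask) {
  idx <- which(mask == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask has no lesion pixels")
  rbar <- mean(idx[, 1]); cbar <- mean(idx[, 2])
  u <- idx[, 2] - cbar; v <- idx[, 1] - rbar
  mu20 <- mean(u^2); mu02 <- mean(v^2); mu11 <- mean(u * v)
  list(center = c(row = rbar, col = cbar),
       mu20 = mu20, mu02 = mu02, mu11 = mu11,
       theta = 0.5 * atan2(2 * mu11, mu20 - mu02))
}

# Bilateral symmetry score about one axis (angle theta through the
# centroid). The reflected mask is rasterized by inverse mapping (a pixel
# belongs to the reflection iff its mirror image falls on a lesion pixel),
# which avoids the holes a forward point-mapping would alias in. FS is the
# symmetric-difference area, A the union area; score = 1 - FS/A
# (1 = self-coincident, 0 = disjoint).
symmetry_about_axis <- function(mask, theta, center) {
  idx <- which(mask == 1, arr.ind = TRUE)
  e <- c(cos(theta), sin(theta))
  # region that can contain the reflection: reflect the mask bbox corners
  corners_u <- range(idx[, 2]) - center[2]
  corners_v <- range(idx[, 1]) - center[1]
  cu <- rep(corners_u, each = 2); cv <- rep(corners_v, 2)
  proj <- cu * e[1] + cv * e[2]
  rcu <- 2 * proj * e[1] - cu; rcv <- 2 * proj * e[2] - cv
  rows <- floor(min(rcv) + center[1] - 1):ceiling(max(rcv) + center[1] + 1)
  cols <- floor(min(rcu) + center[2] - 1):ceiling(max(rcu) + center[2] + 1)
  qr <- rep(rows, times = length(cols)); qc <- rep(cols, each = length(rows))
  qu <- qc - center[2]; qv <- qr - center[1]
  qproj <- qu * e[1] + qv * e[2]
  pr <- round(2 * qproj * e[2] - qv + center[1])
  pc <- round(2 * qproj * e[1] - qu + center[2])
  ok <- pr >= 1 & pr <= nrow(mask) & pc >= 1 & pc <= ncol(mask)
  hit <- ok
  hit[ok] <- mask[cbind(pr[ok], pc[ok])] == 1
  key <- function(r, c) r * 100000 + c
  orig <- key(idx[, 1], idx[, 2])
  refl <- key(qr[hit], qc[hit])
  inter <- sum(refl %in% orig)
  a_union <- length(orig) + length(refl) - inter
  fs <- length(orig) + length(refl) - 2 * inter
  1 - fs / a_union
}

#' Bilateral symmetry of a lesion mask
#'
#' Reflects the mask about each of its two principal axes (derived from
#' the second central moments, passing through the centroid) and scores
#' each axis as one minus the ratio of the symmetric-difference area to
#' the union area of the mask and its reflection. The two axis scores are
#' averaged. 1 means perfectly bilaterally symmetric, 0 means the
#' reflection is disjoint from the original.
#'
#' @param mask binary matrix with at least one lesion pixel.
#' @return symmetry score in \[0, 1\].
#' @export
symmetry <- function(mask) {
  validate_mask(mask)
  if (sum(mask) < 1) stop("mask has no lesion pixels")
  mm <- mask_moments(mask)
  s1 <- symmetry_about_axis(mask, mm$theta, mm$center)
  s2 <- symmetry_about_axis(mask, mm$theta + pi / 2, mm$center)
  (s1 + s2) / 2
}

# Contour length of the 0.5-level isoline of the (zero-padded) mask.
# The raw marching-squares polygon overestimates smooth boundaries by a
# few percent (staircase effect); a short circular moving average over the
# vertices removes the stair oscillation and brings the length of digital
# discs within a few tenths of a percent of the true circumference.
mask_perimeter <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  p <- matrix(0, H + 2L, W + 2L)
  p[2:(H + 1), 2:(W + 1)] <- mask
  cl <- grDevices::contourLines(x = seq_len(H + 2L), y = seq_len(W + 2L),
                                z = p, levels = 0.5)
  total <- 0
  for (cc in cl) {
    x <- cc$x; y <- cc$y; n <- length(x)
    if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
    w <- 2L
    if (n >= 2L * w + 1L) {
      idx <- function(i) ((i - 1L) %% n) + 1L
      x <- vapply(1:n, function(i) mean(cc$x[idx((i - w):(i + w))]), 0)
      y <- vapply(1:n, function(i) mean(cc$y[idx((i - w):(i + w))]), 0)
    }
    total <- total + sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  }
  total
}

#' Shape descriptors of a lesion mask
#'
#' Area (pixel count), perimeter (length of the traced lesion contour),
#' circularity `4*pi*area/perimeter^2`, diameter (major-axis length of the
#' image-moment ellipse, `4*sqrt(lambda1)` for the leading eigenvalue of
#' the second-central-moment matrix), eccentricity
#' `sqrt(1 - lambda2/lambda1)`, and the bilateral [symmetry()] score.
#'
#' @param mask binary matrix with at least 4 lesion pixels.
#' @return named list of class `shape_features` with elements `area`,
#'   `perimeter`, `circularity`, `diameter`, `eccentricity`, `symmetry`.
#' @export
shape_features <- function(mask) {
  validate_mask(mask)
  if (sum(mask) < 4) stop("mask must contain at least 4 lesion pixels")
  area <- sum(mask)
  perim <- mask_perimeter(mask)
  mm <- mask_moments(mask)
  M <- matrix(c(mm$mu20, mm$mu11, mm$mu11, mm$mu02), 2, 2)
  ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  if (ev[1] <= 0) {
    warning("degenerate mask: moment ellipse is a point; eccentricity set to 1")
    diam <- 1; ecc <- 1
  } else {
    diam <- 4 * sqrt(ev[1])
    if (ev[2] <= 0) {
      warning("degenerate 1-pixel-wide mask: eccentricity clamped to 1")
      ecc <- 1
    } else ecc <- sqrt(1 - ev[2] / ev[1])
  }
  out <- list(area = area, perimeter = perim,
              circularity = 4 * pi * area / perim^2,
              diameter = diam, eccentricity = ecc,
              symmetry = symmetry(mask))
  class(out) <- "shape_features"
  out
}

#' Color statistics over RGB and CIELab channels
#'
#' Minimum, maximum, population variance, and mean of each of the six
#' channels R, G, B, L, a*, b*, computed over the lesion pixels of the ROI
#' (default) or over the whole crop. 24 values in channel-major order
#' (`R_min, R_max, R_var, R_mean, G_min, ...`).
#'
#' @param roi a `roi_patch` from [preprocess()].
#' @param lesion_only restrict statistics to lesion pixels (default TRUE).
#' @return named numeric vector of length 24.
#' @export
color_features <- function(roi, lesion_only = TRUE) {
  stopifnot(inherits(roi, "roi_patch"))
  chans <- list(R = roi$rgb[, , 1], G = roi$rgb[, , 2], B = roi$rgb[, , 3],
                L = roi$lab$L, a = roi$lab$a, b = roi$lab$b)
  sel <- if (lesion_only) roi$mask == 1 else rep(TRUE, length(roi$mask))
  out <- numeric(0)
  for (nm in names(chans)) {
    v <- chans[[nm]][sel]
    st <- c(min = min(v), max = max(v),
            var = mean((v - mean(v))^2), mean = mean(v))
    names(st) <- paste(nm, names(st), sep = "_")
    out <- c(out, st)
  }
  out
}

#' The full 43-element handcrafted feature vector
#'
#' Fixed, documented order: `symmetry`, `area`, `perimeter`, `circularity`,
#' `diameter`, `eccentricity`, the 24 [color_features()] (channel-major
#' over R, G, B, L, a*, b*), and the 13 averaged Haralick
#' [texture_features()].
#'
#' @param roi a `roi_patch` from [preprocess()].
#' @param lesion_only compute color/texture statistics over lesion pixels
#'   only (default TRUE) or over the whole crop.
#' @param n_levels,distance,angles GLCM settings passed to
#'   [texture_features()].
#' @return named numeric vector of length 43.
#' @examples
#' img <- make_lesion_image(synthetic_lesion_spec(image_size = c(96, 128),
#'                                                seed = 1))$image
#' h <- handcraft_vector(preprocess(img))
#' length(h)  # 43
#' @export
handcraft_vector <- function(roi, lesion_only = TRUE, n_levels = 32L,
                             distance = 1L, angles = c(0, 45, 90, 135)) {
  stopifnot(inherits(roi, "roi_patch"))
  sf <- shape_features(roi$mask)
  shape <- c(symmetry = sf$symmetry, area = sf$area, perimeter = sf$perimeter,
             circularity = sf$circularity, diameter = sf$diameter,
             eccentricity = sf$eccentricity)
  col <- color_features(roi, lesion_only = lesion_only)
  gray <- quantize_gray(gray_from_rgb(roi$rgb), n_levels)
  tex <- texture_features(gray, mask = if (lesion_only) roi$mask else NULL,
                          n_levels = n_levels, distance = distance,
                          angles = angles)
  out <- c(shape, col, tex)
  stopifnot(length(out) == 43L)
  out
}

#' Total Dermatoscopic Score (TDS)
#'
#' Weighted clinical ABCD score `1.3*A + 0.1*B + 0.5*C + 0.5*D` with the
#' standard interpretation: below 4.75 benign, 4.75 to 5.45 suspicious,
#' above 5.45 malignant.
#'
#' @param asymmetry integer 0-2 (axes showing asymmetry).
#' @param borders integer 0-8 (segments with abrupt borders).
#' @param colors integer 1-6 (distinct colors present).
#' @param structures integer 1-4 (dermatoscopic structures present).
#' @return list with `score` and `category`
#'   (`"benign"`, `"suspicious"`, or `"malignant"`).
#' @examples
#' tds_score(2, 8, 6, 4)  # 8.4, malignant
#' @export
tds_score <- function(asymmetry, borders, colors, structures) {
  chk <- function(x, lo, hi, nm) {
    if (length(x) != 1L || is.na(x) || x != round(x) || x < lo || x > hi)
      stop(sprintf("%s must be an integer in [%d, %d]", nm, lo, hi))
  }
  chk(asymmetry, 0, 2, "asymmetry"); chk(borders, 0, 8, "borders")
  chk(colors, 1, 6, "colors"); chk(structures, 1, 4, "structures")
  score <- 1.3 * asymmetry + 0.1 * borders + 0.5 * colors + 0.5 * structures
  category <- if (score < 4.75) "benign"
              else if (score <= 5.45) "suspicious" else "malignant"
  list(score = score, category = category)
}
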