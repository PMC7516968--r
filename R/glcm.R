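#' Gray-level co-occurrence texture
#'
#' Texture is summarized by Haralick statistics of the gray-level
#' co-occurrence matrix (GLCM): the joint distribution of quantized gray
#' levels of pixel pairs at a fixed spatial offset. Thirteen statistics are
#' computed per offset and averaged over the configured offsets (default
#' distance 1 at 0, 45, 90, 135 degrees, accumulated symmetrically).
#'
#' @name glcm-module
NULL

#' Luminance of an RGB array
#'
#' Classic luma weighting `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param rgb H x W x 3 array in \[0, 255\].
#' @return H x W numeric matrix in \[0, 255\].
#' @export
gray_from_rgb <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

#' Quantize a grayscale image to a fixed number of levels
#'
#' Equal-width quantization of the fixed \[0, 255\] intensity range into
#' `n_levels` levels `0 .. n_levels - 1`.
#'
#' @param gray numeric matrix in \[0, 255\].
#' @param n_levels number of gray levels.
#' @return integer matrix with values in `[0, n_levels)`.
#' @export
quantize_gray <- function(gray, n_levels = 32L) {
  q <- floor(gray / 256 * n_levels)
  q[q > n_levels - 1L] <- n_levels - 1L
  q[q < 0L] <- 0L
  storage.mode(q) <- "integer"
  q
}

# (distance, angle in degrees) -> (row, col) displacement
offset_from_angle <- function(distance, angle) {
  switch(as.character(angle %% 180),
         "0"   = c(0L, distance),
         "45"  = c(-distance, distance),
         "90"  = c(-distance, 0L),
         "135" = c(-distance, -distance),
         stop("supported angles are 0, 45, 90, 135 degrees"))
}

#' Gray-level co-occurrence matrix
#'
#' Accumulates co-occurrence counts of quantized gray levels over the given
#' pixel offsets, symmetrically (each pair is counted in both directions),
#' and normalizes to a probability matrix. When a mask is supplied, only
#' pairs with both pixels inside the mask contribute, so texture is a
#' property of the lesion rather than of the rectangular crop.
#'
#' @param gray integer matrix with values in `[0, n_levels)`.
#' @param n_levels number of gray levels.
#' @param offsets list of `c(row_offset, col_offset)` displacements.
#' @param mask optional binary matrix restricting contributing pixels.
#' @return object of class `glcm`: list with `Pd` (n_levels x n_levels
#'   probability matrix summing to 1), `n_levels`, `offsets`.
#' @export
glcm <- function(gray, n_levels = 32L, offsets = list(c(0L, 1L)),
                 mask = NULL) {
  if (!is.matrix(gray)) stop("gray must be a matrix")
  if (min(gray) < 0 || max(gray) > n_levels - 1L)
    stop("gray values must lie in [0, n_levels)")
  H <- nrow(gray); W <- ncol(gray)
  counts <- matrix(0, n_levels, n_levels)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1L, 1L - dr):min(H, H - dr)
    c1 <- max(1L, 1L - dc):min(W, W - dc)
    a <- gray[r1, c1, drop = FALSE]
    b <- gray[r1 + dr, c1 + dc, drop = FALSE]
    if (!is.null(mask)) {
      ok <- (mask[r1, c1, drop = FALSE] == 1) &
            (mask[r1 + dr, c1 + dc, drop = FALSE] == 1)
      a <- a[ok]; b <- b[ok]
    }
    if (length(a)) {
      tab <- table(factor(a, levels = 0:(n_levels - 1L)),
                   factor(b, levels = 0:(n_levels - 1L)))
      counts <- counts + tab + t(tab)   # symmetric accumulation
    }
  }
  if (sum(counts) == 0) stop("no valid pixel pairs for the GLCM")
  out <- list(Pd = counts / sum(counts), n_levels = as.integer(n_levels),
              offsets = offsets)
  class(out) <- "glcm"
  out
}

#' Thirteen Haralick texture statistics of a GLCM
#'
#' Computes, from the normalized co-occurrence matrix: angular second
#' moment, contrast, correlation, variance, inverse difference moment,
#' entropy, sum average, sum variance, sum entropy, difference variance,
#' difference entropy, and the two informational measures of correlation.
#' Natural logarithms are used throughout, with `0 * log 0 = 0`. For a
#' single-cell (constant-image) distribution correlation and the first
#' informational measure are defined as 0.
#'
#' @param g a [glcm()] object.
#' @return named numeric vector of length 13 in the order `asm`,
#'   `contrast`, `correlation`, `variance`, `idm`, `entropy`,
#'   `sum_average`, `sum_variance`, `sum_entropy`, `difference_variance`,
#'   `difference_entropy`, `imcorr1`, `imcorr2`.
#' @export
haralick_features <- function(g) {
  stopifnot(inherits(g, "glcm"))
  P <- g$Pd
  if (sum(P) == 0) stop("GLCM is all zero")
  Ng <- g$n_levels
  i <- matrix(rep(1:Ng, Ng), Ng, Ng)       # row index
  j <- t(i)
  xlnx <- function(p) ifelse(p > 0, p * log(p), 0)

  mu_x <- sum(i * P); mu_y <- sum(j * P)
  s_x <- sqrt(sum((i - mu_x)^2 * P)); s_y <- sqrt(sum((j - mu_y)^2 * P))

  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (s_x * s_y > 0)
    sum((i - mu_x) * (j - mu_y) * P) / (s_x * s_y) else 0
  variance <- sum((i - mu_x)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  entropy <- -sum(xlnx(P))

  k_sum <- 2:(2 * Ng)
  p_sum <- vapply(k_sum, function(k) sum(P[i + j == k]), numeric(1))
  sum_average <- sum(k_sum * p_sum)
  sum_variance <- sum((k_sum - sum_average)^2 * p_sum)
  sum_entropy <- -sum(xlnx(p_sum))

  k_diff <- 0:(Ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  mu_diff <- sum(k_diff * p_diff)
  difference_variance <- sum((k_diff - mu_diff)^2 * p_diff)
  difference_entropy <- -sum(xlnx(p_diff))

  px <- rowSums(P); py <- colSums(P)
  hx <- -sum(xlnx(px)); hy <- -sum(xlnx(py))
  hxy <- entropy
  pxpy <- outer(px, py)
  hxy1 <- -sum(ifelse(P > 0 & pxpy > 0, P * log(pxpy), 0))
  hxy2 <- -sum(xlnx(pxpy))
  imcorr1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imcorr2 <- 1 - exp(-2 * (hxy2 - hxy))
  imcorr2 <- min(max(imcorr2, 0), 1)

  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, entropy = entropy,
    sum_average = sum_average, sum_variance = sum_variance,
    sum_entropy = sum_entropy, difference_variance = difference_variance,
    difference_entropy = difference_entropy, imcorr1 = imcorr1,
    imcorr2 = imcorr2)
}

#' Averaged Haralick features over a set of offsets
#'
#' Builds one GLCM per (distance, angle) offset and averages the 13
#' [haralick_features()] over the offsets, the rotation-robust convention.
#'
#' @param gray quantized integer matrix (see [quantize_gray()]).
#' @param mask optional binary matrix restricting contributing pixels.
#' @param n_levels number of gray levels.
#' @param distance pixel displacement distance.
#' @param angles angles in degrees (subset of 0, 45, 90, 135).
#' @return named numeric vector of length 13.
#' @export
texture_features <- function(gray, mask = NULL, n_levels = 32L,
                             distance = 1L, angles = c(0, 45, 90, 135)) {
  feats <- vapply(angles, function(a) {
    g <- glcm(gray, n_levels = n_levels,
              offsets = list(offset_from_angle(distance, a)), mask = mask)
    haralick_features(g)
  }, numeric(13))
  rowMeans(feats)
}
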