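#' Lesion segmentation and ROI extraction
#'
#' The preprocessing stage turns a raw RGB dermoscopy image into a cropped
#' region of interest (ROI) with a binary lesion mask. The sequence is:
#' Gaussian blur (artifact suppression), conversion to CIELab, mean
#' thresholding of each of the L, a*, b* channels, intersection of the three
#' binary maps, a 5x5 majority (median) filter, polarity/component resolution
#' of the lesion, and a tight bounding box used to crop the RGB image, its
#' Lab representation, and the mask.
#'
#' @name preprocess-module
NULL

validate_rgb <- function(img, min_size = 1L) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected an H x W x 3 RGB array")
  if (dim(img)[1] < min_size || dim(img)[2] < min_size)
    stop(sprintf("image must be at least %d x %d pixels", min_size, min_size))
  if (min(img) < 0 || max(img) > 255)
    stop("RGB intensities must lie in [0, 255]")
  invisible(img)
}

validate_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!all(mask %in% c(0, 1))) stop("mask values must be exactly 0 or 1")
  invisible(mask)
}

#' Gaussian blur of an RGB image
#'
#' Convolves each channel with an isotropic 2-D Gaussian kernel of standard
#' deviation `sigma` (replicated borders), clipping the result to
#' \[0, 255\]. Used to suppress hair and other curvilinear artifacts before
#' thresholding while preserving the lesion geometry.
#'
#' @param img H x W x 3 numeric array with values in \[0, 255\].
#' @param sigma positive kernel standard deviation in pixels.
#' @return blurred array of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma) {
  validate_rgb(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a positive number")
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  k <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  out <- img
  for (ch in 1:3)
    out[, , ch] <- EBImage::filter2(img[, , ch], k, boundary = "replicate")
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

#' Convert an RGB image to CIELab
#'
#' Standard sRGB (D65 white point) to CIEL*a*b* conversion. L lies in
#' \[0, 100\]; a* and b* are chroma axes (magenta-green, blue-yellow).
#'
#' @param img H x W x 3 numeric array with values in \[0, 255\].
#' @return object of class `lab_image`: a list with H x W matrices `L`,
#'   `a`, `b`.
#' @export
rgb_to_lab <- function(img) {
  validate_rgb(img)
  d <- dim(img)
  flat <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                as.vector(img[, , 3])) / 255
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
  out <- list(L = matrix(lab[, 1], d[1], d[2]),
              a = matrix(lab[, 2], d[1], d[2]),
              b = matrix(lab[, 3], d[1], d[2]))
  class(out) <- "lab_image"
  out
}

#' Threshold a channel at its mean
#'
#' Marks every pixel whose value is greater than or equal to the channel
#' mean as 1, else 0. Applied independently to L, a*, b* during
#' segmentation so that bright/chromatic healthy skin separates from the
#' darker lesion.
#'
#' @param channel numeric matrix.
#' @return binary matrix of the same size.
#' @export
mean_threshold_channel <- function(channel) {
  if (!is.matrix(channel) || length(channel) == 0L)
    stop("channel must be a non-empty matrix")
  (channel >= mean(channel)) + 0L
}

#' Intersect three binary masks
#'
#' Pixelwise logical AND of the per-channel threshold maps.
#'
#' @param mL,ma,mb binary matrices of identical size.
#' @return binary matrix.
#' @export
combine_masks <- function(mL, ma, mb) {
  validate_mask(mL); validate_mask(ma); validate_mask(mb)
  if (!all(dim(mL) == dim(ma)) || !all(dim(mL) == dim(mb)))
    stop("mask dimensions differ")
  (mL & ma & mb) + 0L
}

#' Majority (median) filter on a binary mask
#'
#' Each output pixel is the majority vote of the `size` x `size` window
#' centred on it; for binary input this is exactly the median filter.
#' Near the border the vote runs over the in-bounds part of the window,
#' so a solid mask is preserved up to its edges while isolated specks are
#' removed.
#'
#' @param mask binary matrix.
#' @param size odd window side length, at least 3 (default 5).
#' @return filtered binary matrix.
#' @export
median_filter_mask <- function(mask, size = 5L) {
  validate_mask(mask)
  size <- as.integer(size)
  if (is.na(size) || size < 3L || size %% 2L == 0L)
    stop("size must be an odd integer >= 3")
  r <- (size - 1L) %/% 2L
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0, H + 2L * r, W + 2L * r)
  pad[(r + 1L):(r + H), (r + 1L):(r + W)] <- mask
  ones <- matrix(0, H + 2L * r, W + 2L * r)
  ones[(r + 1L):(r + H), (r + 1L):(r + W)] <- 1
  win <- function(p) {
    # summed-area table; S[i+1, j+1] = sum(p[1:i, 1:j])
    S <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
    S[-1, -1] <- t(apply(apply(p, 2, cumsum), 1, cumsum))
    ih <- 1:H; jh <- 1:W
    S[ih + 2L * r + 1L, jh + 2L * r + 1L, drop = FALSE] -
      S[ih, jh + 2L * r + 1L, drop = FALSE] -
      S[ih + 2L * r + 1L, jh, drop = FALSE] + S[ih, jh, drop = FALSE]
  }
  votes <- win(pad)
  denom <- win(ones)
  (2 * votes > denom) + 0L
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so
# diagonally adjacent labels are merged with a union-find pass.
label_components8 <- function(m) {
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(m)))
  n <- max(lab)
  if (n <= 1L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  dr <- cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1]))   # down-right
  dl <- cbind(as.vector(lab[-H, -1]), as.vector(lab[-1, -W]))   # down-left
  pr <- rbind(dr, dl)
  pr <- unique(pr[pr[, 1] > 0 & pr[, 2] > 0 & pr[, 1] != pr[, 2], , drop = FALSE])
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  if (nrow(pr)) for (q in seq_len(nrow(pr))) {
    a <- find(pr[q, 1]); b <- find(pr[q, 2])
    if (a != b) parent[b] <- a
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- lab
  out[lab > 0] <- root[lab[lab > 0]]
  out
}

#' Resolve which region of a thresholded mask is the lesion
#'
#' The CIELab mean-threshold intersection marks bright skin with 1 and the
#' darker lesion with 0, but polarity can flip for unusual palettes and the
#' map may contain several regions. The lesion is taken to be the largest
#' 8-connected component, over both foreground and background components,
#' that does not touch the image border (lesions are interior, skin reaches
#' the frame). If every candidate touches the border, the largest component
#' overall is returned with a warning.
#'
#' Before labelling, each polarity is cleaned by a morphological opening
#' with a small disc, which removes residual curvilinear artifacts (hair
#' fragments) that are too wide for the majority filter but much thinner
#' than any lesion; set `clean_brush = 0` to disable.
#'
#' @param binmask binary matrix containing both values.
#' @param clean_brush disc diameter (odd, pixels) of the opening applied
#'   to each polarity before component labelling; 0 disables cleaning.
#' @return binary matrix with lesion pixels set to 1.
#' @export
lesion_mask <- function(binmask, clean_brush = 5L) {
  validate_mask(binmask)
  if (length(unique(as.vector(binmask))) < 2L)
    stop("no lesion found: thresholded mask is uniform")
  H <- nrow(binmask); W <- ncol(binmask)
  polarities <- list(binmask, 1L - binmask)
  if (clean_brush >= 3L) {
    brush <- EBImage::makeBrush(as.integer(clean_brush), shape = "disc")
    opened <- lapply(polarities, function(p)
      round(EBImage::imageData(EBImage::opening(p, brush))))
    if (any(vapply(opened, sum, numeric(1)) > 0)) polarities <- opened
  }
  cand <- list()
  for (pol in polarities) {
    lab <- label_components8(pol)
    for (id in setdiff(unique(as.vector(lab)), 0L)) {
      sel <- lab == id
      border <- any(sel[1, ]) || any(sel[H, ]) || any(sel[, 1]) || any(sel[, W])
      cand[[length(cand) + 1L]] <- list(mask = sel, size = sum(sel),
                                        border = border)
    }
  }
  sizes <- vapply(cand, `[[`, numeric(1), "size")
  interior <- !vapply(cand, `[[`, logical(1), "border")
  if (any(interior)) {
    pick <- which(interior)[which.max(sizes[interior])]
  } else {
    warning("no interior component found; falling back to largest component")
    pick <- which.max(sizes)
  }
  out <- cand[[pick]]$mask + 0L
  if (clean_brush >= 3L) {
    # second, size-adaptive opening: artifacts attached to the lesion are
    # thin relative to the lesion itself, so a brush scaling with the
    # component diameter removes hair appendages without reshaping the blob
    d <- max(as.integer(clean_brush),
             2L * as.integer(sqrt(sum(out)) / 30) + 1L)
    op <- round(EBImage::imageData(
      EBImage::opening(out, EBImage::makeBrush(d, shape = "disc"))))
    if (sum(op) > 0) {
      lab <- label_components8(op)
      sz <- tabulate(lab[lab > 0])
      out <- (lab == which.max(sz)) + 0L
    }
  }
  out
}

#' Tight bounding box of a binary mask
#'
#' Coordinates are 0-based and half-open: the box spans rows
#' `[row_min, row_max)` and columns `[col_min, col_max)`.
#'
#' @param mask binary matrix with at least one 1-pixel.
#' @return object of class `bounding_box`: list with `row_min`, `col_min`,
#'   `row_max`, `col_max`.
#' @export
bounding_box <- function(mask) {
  validate_mask(mask)
  idx <- which(mask == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask has no lesion pixels")
  out <- list(row_min = min(idx[, 1]) - 1L, col_min = min(idx[, 2]) - 1L,
              row_max = max(idx[, 1]), col_max = max(idx[, 2]))
  class(out) <- "bounding_box"
  out
}

crop_box <- function(x, box) {
  rows <- (box$row_min + 1L):box$row_max
  cols <- (box$col_min + 1L):box$col_max
  if (length(dim(x)) == 3L) x[rows, cols, , drop = FALSE]
  else x[rows, cols, drop = FALSE]
}

#' Segment a dermoscopy image and extract the ROI
#'
#' Runs the full preprocessing chain: Gaussian blur, CIELab conversion,
#' per-channel mean thresholding, mask intersection, 5x5 majority filter,
#' lesion polarity/component resolution, and bounding-box cropping. The
#' returned crops are taken from the *original* (unblurred) image; the blur
#' only stabilizes segmentation.
#'
#' @param img H x W x 3 numeric array with values in \[0, 255\].
#' @param sigma Gaussian blur standard deviation in pixels (default 3).
#' @param median_size majority-filter window (default 5).
#' @return object of class `roi_patch`: list with `rgb` (cropped RGB array),
#'   `lab` (cropped `lab_image`), `mask` (cropped binary lesion mask),
#'   `box` (`bounding_box` on the source image), and `sigma`.
#' @examples
#' img <- make_lesion_image(synthetic_lesion_spec(image_size = c(96, 128),
#'                                                seed = 1))$image
#' roi <- preprocess(img)
#' dim(roi$rgb)
#' @export
preprocess <- function(img, sigma = 3, median_size = 5L) {
  validate_rgb(img, min_size = 16L)
  blurred <- gaussian_blur(img, sigma)
  lab_b <- rgb_to_lab(blurred)
  m <- combine_masks(mean_threshold_channel(lab_b$L),
                     mean_threshold_channel(lab_b$a),
                     mean_threshold_channel(lab_b$b))
  m <- median_filter_mask(m, median_size)
  lesion <- lesion_mask(m)
  if (sum(lesion) < 25)
    warning("detected lesion is smaller than 25 pixels")
  box <- bounding_box(lesion)
  rgb_crop <- crop_box(img, box)
  lab_full <- rgb_to_lab(rgb_crop)
  out <- list(rgb = rgb_crop, lab = lab_full,
              mask = crop_box(lesion, box), box = box, sigma = sigma)
  class(out) <- "roi_patch"
  out
}

#' @export
print.roi_patch <- function(x, ...) {
  cat(sprintf("ROI patch: %d x %d px, %d lesion pixels, box [%d,%d)x[%d,%d)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              x$box$row_min, x$box$row_max, x$box$col_min, x$box$col_max))
  invisible(x)
}

#' Read an image file into an RGB array
#'
#' Reads a PNG (via the png package) or TIFF image and returns an
#' H x W x 3 array scaled to \[0, 255\]. Grayscale images are replicated
#' across channels; an alpha channel is dropped.
#'
#' @param path file path.
#' @return H x W x 3 numeric array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) {
    x <- png::readPNG(path)
  } else {
    stop("unsupported image format '", ext, "': only PNG input is supported")
  }
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] == 2L) x <- array(rep(x[, , 1], 3L), c(dim(x)[1:2], 3L))
  x * 255
}

#' Write a binary mask as a PNG file
#'
#' @param mask binary matrix; written as an 8-bit grayscale PNG with
#'   lesion pixels at 255.
#' @param path output file path.
#' @export
write_mask <- function(mask, path) {
  validate_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}
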