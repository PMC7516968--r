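#' Synthetic dermoscopy-like images and feature tables
#'
#' Deterministic generators used throughout the test suite and examples:
#' a lesion-image generator producing a darker, optionally asymmetric
#' elliptical lesion on lighter skin with a multi-color interior, hair-like
#' arcs and pixel noise, together with its ground-truth mask; and a feature
#' table generator with a known number of informative columns.
#'
#' @name synth-module
NULL

#' Clinically motivated lesion palette
#'
#' Returns `n` (1-6) RGB colors drawn from the shades reported in pigmented
#' lesions: light brown, dark brown, black, blue-gray, red, white.
#'
#' @param n number of colors (1-6).
#' @return n x 3 matrix of RGB values in \[0, 255\].
#' @export
lesion_palette <- function(n = 2L) {
  # ordered so that the leading colors sit below typical skin on all of
  # L, a*, b*, the regime the CIELab mean-threshold segmentation targets;
  # red and light brown (high chroma) come last
  cols <- rbind(
    c( 82,  52,  38),   # dark brown
    c( 45,  32,  28),   # black-brown
    c(110,  78,  62),   # gray-brown
    c( 80,  85, 105),   # blue-gray
    c(140,  60,  55),   # red
    c(150, 100,  60))   # light brown
  if (n < 1L || n > 6L) stop("palette supports 1 to 6 colors")
  cols[seq_len(n), , drop = FALSE]
}

#' Specification of a synthetic lesion image
#'
#' Defaults emulate the dermoscopy images the pipeline targets: a 450 x 600
#' RGB canvas with a centred, rotated, darker elliptical lesion on lighter
#' skin and mild sensor noise.
#'
#' @param image_size c(H, W) canvas in pixels.
#' @param center lesion centre c(row, col); default canvas centre.
#' @param semi_axes ellipse semi-axes c(a, b) in pixels; default scales with
#'   the canvas.
#' @param rotation ellipse rotation in degrees.
#' @param asymmetry_level boundary perturbation amplitude in \[0, 1\]; a
#'   one-sided sinusoidal radial bump, so measured bilateral symmetry
#'   decreases monotonically with this level.
#' @param n_colors number of lesion palette colors (1-6).
#' @param palette optional n x 3 RGB matrix overriding [lesion_palette()].
#' @param palette_weights mixture weights over palette colors.
#' @param skin_color background skin RGB triple.
#' @param hair_count number of dark hair-like arcs drawn over the image.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (intensity units).
#' @param seed integer seed; the generator is fully deterministic per seed.
#' @return list of class `synthetic_lesion_spec`.
#' @export
synthetic_lesion_spec <- function(image_size = c(450L, 600L), center = NULL,
                                  semi_axes = NULL, rotation = 25,
                                  asymmetry_level = 0, n_colors = 2L,
                                  palette = NULL, palette_weights = NULL,
                                  skin_color = c(224, 172, 150),
                                  hair_count = 0L, noise_sd = 2, seed = 1L) {
  image_size <- as.integer(image_size)
  if (is.null(center)) center <- image_size / 2
  if (is.null(semi_axes)) semi_axes <- round(image_size * c(0.20, 0.20))
  if (asymmetry_level < 0 || asymmetry_level > 1)
    stop("asymmetry_level must be in [0, 1]")
  if (is.null(palette)) palette <- lesion_palette(n_colors)
  if (is.null(palette_weights)) palette_weights <- rep(1, nrow(palette))
  palette_weights <- palette_weights / sum(palette_weights)
  # maximal radial extent including the asymmetry bump must stay >= 5 px
  # inside the canvas
  reach <- max(semi_axes) * (1 + 0.5 * asymmetry_level)
  if (center[1] - reach < 5 || center[1] + reach > image_size[1] - 5 ||
      center[2] - reach < 5 || center[2] + reach > image_size[2] - 5)
    stop("ellipse (with asymmetry bump) does not fit inside the image")
  out <- list(image_size = image_size, center = center, semi_axes = semi_axes,
              rotation = rotation, asymmetry_level = asymmetry_level,
              palette = palette, palette_weights = palette_weights,
              skin_color = skin_color, hair_count = as.integer(hair_count),
              noise_sd = noise_sd, seed = as.integer(seed))
  class(out) <- "synthetic_lesion_spec"
  out
}

# True lesion membership: normalized elliptical radius against the
# one-sided perturbed boundary.
lesion_membership <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  th <- spec$rotation * pi / 180
  r <- matrix(rep(seq_len(H), W), H, W) - spec$center[1]
  c_ <- matrix(rep(seq_len(W), each = H), H, W) - spec$center[2]
  u <- cos(th) * c_ + sin(th) * r      # along major axis
  v <- -sin(th) * c_ + cos(th) * r
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]
  e <- sqrt((u / a)^2 + (v / b)^2)
  phi <- atan2(v / b, u / a)
  bump <- 1 + 0.5 * spec$asymmetry_level * sin(phi) * (phi > 0 & phi < pi)
  (e <= bump) + 0L
}

#' Generate a synthetic lesion image with ground truth
#'
#' Renders a skin-colored background, a radially perturbed dark ellipse
#' whose interior is tiled with blobby patches of the palette colors,
#' optional dark hair-like quadratic arcs, and additive Gaussian noise.
#'
#' @param spec a [synthetic_lesion_spec()].
#' @return list with `image` (H x W x 3 array in \[0, 255\]), `mask`
#'   (ground-truth binary lesion mask), and `attributes` (true area, axis
#'   lengths, asymmetry level, palette).
#' @export
make_lesion_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_lesion_spec"))
  with_local_seed(spec$seed, {
    H <- spec$image_size[1]; W <- spec$image_size[2]
    mask <- lesion_membership(spec)
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) img[, , ch] <- spec$skin_color[ch]

    idx <- which(mask == 1, arr.ind = TRUE)
    ncol_pal <- nrow(spec$palette)
    if (ncol_pal == 1L) {
      assign_col <- rep(1L, nrow(idx))
    } else {
      # blobby interior: weighted Voronoi patches around random seed points
      nseed <- 8L * ncol_pal
      seeds <- idx[sample.int(nrow(idx), min(nseed, nrow(idx))), , drop = FALSE]
      seed_col <- sample.int(ncol_pal, nrow(seeds), replace = TRUE,
                             prob = spec$palette_weights)
      d2 <- outer(idx[, 1], seeds[, 1], `-`)^2 + outer(idx[, 2], seeds[, 2], `-`)^2
      assign_col <- seed_col[max.col(-d2, ties.method = "first")]
    }
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- spec$palette[assign_col, ch]
      img[, , ch] <- plane
    }

    if (spec$hair_count > 0L) {
      for (h in seq_len(spec$hair_count)) {
        p0 <- c(runif(1, 1, H), runif(1, 1, W))
        p2 <- c(runif(1, 1, H), runif(1, 1, W))
        p1 <- (p0 + p2) / 2 + runif(2, -0.35, 0.35) * c(H, W)
        tt <- seq(0, 1, length.out = 4L * ceiling(sqrt(sum((p2 - p0)^2))))
        pts <- cbind((1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * p1[1] + tt^2 * p2[1],
                     (1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * p1[2] + tt^2 * p2[2])
        # two stroke styles: thin dark (1 px) and wider faint (2-3 px).
        # Both stay within the contrast/width regime that Gaussian blur
        # plus the 5x5 majority filter can suppress during segmentation;
        # wide fully opaque occlusions defeat mean thresholding and are
        # outside the artifact class this generator emulates.
        w <- sample(1:2, 1)
        alpha <- if (w == 1L) 0.6 else 0.2
        off <- expand.grid(dr = -w:w, dc = -w:w)
        off <- off[off$dr^2 + off$dc^2 <= (w / 2)^2 + 0.5, , drop = FALSE]
        rr <- rep(round(pts[, 1]), nrow(off)) + rep(off$dr, each = nrow(pts))
        cc <- rep(round(pts[, 2]), nrow(off)) + rep(off$dc, each = nrow(pts))
        ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
        hp <- unique(cbind(rr[ok], cc[ok]))  # blend each pixel once
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[hp] <- (1 - alpha) * plane[hp] + alpha * c(60, 45, 35)[ch]
          img[, , ch] <- plane
        }
      }
    }

    if (spec$noise_sd > 0)
      img <- img + array(rnorm(length(img), sd = spec$noise_sd), dim(img))
    img[img < 0] <- 0
    img[img > 255] <- 255

    list(image = img, mask = mask,
         attributes = list(area = sum(mask),
                           axis_lengths = 2 * spec$semi_axes,
                           asymmetry_level = spec$asymmetry_level,
                           center = spec$center, rotation = spec$rotation,
                           palette = spec$palette))
  })
}

#' Specification of a synthetic labelled feature table
#'
#' @param n number of instances.
#' @param p number of features.
#' @param n_informative number of columns carrying a class-conditional mean
#'   shift; the remaining columns are label-independent standard normal.
#' @param class_balance minority-class fraction in (0, 0.5\]; the minority
#'   count is fixed (not binomial).
#' @param effect_size standardized mean shift of informative columns.
#' @param seed integer seed.
#' @return list of class `synthetic_table_spec`.
#' @export
synthetic_table_spec <- function(n = 2000L, p = 1000L, n_informative = 10L,
                                 class_balance = 0.5, effect_size = 3,
                                 seed = 1L) {
  if (n_informative > p) stop("n_informative must not exceed p")
  if (class_balance <= 0 || class_balance > 0.5)
    stop("class_balance must be in (0, 0.5]")
  out <- list(n = as.integer(n), p = as.integer(p),
              n_informative = as.integer(n_informative),
              class_balance = class_balance, effect_size = effect_size,
              seed = as.integer(seed))
  class(out) <- "synthetic_table_spec"
  out
}

#' Generate a labelled feature table with known informative columns
#'
#' Informative columns are standard normal plus `effect_size` for the
#' positive (minority) class; noise columns are standard normal regardless
#' of the label. The minority count is exactly `round(class_balance * n)`.
#'
#' @param spec a [synthetic_table_spec()].
#' @return a [feature_matrix()] whose informative columns are named
#'   `inf_*` and noise columns `noise_*`.
#' @export
make_feature_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_table_spec"))
  with_local_seed(spec$seed, {
    n_min <- round(spec$class_balance * spec$n)
    y <- sample(c(rep(1L, n_min), rep(0L, spec$n - n_min)))
    X <- matrix(rnorm(spec$n * spec$p), spec$n, spec$p)
    if (spec$n_informative > 0)
      X[, seq_len(spec$n_informative)] <-
        X[, seq_len(spec$n_informative), drop = FALSE] + spec$effect_size * y
    nm <- c(sprintf("inf_%d", seq_len(spec$n_informative)),
            sprintf("noise_%d", seq_len(spec$p - spec$n_informative)))
    feature_matrix(X, y, nm)
  })
}
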