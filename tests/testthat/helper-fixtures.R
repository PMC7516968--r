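# Shared fixtures and independent brute-force oracles. Oracles are written
# as plain double loops straight from the defining formulas, independent of
# the package implementation they check.

disc_mask <- function(size, r, center = c(size, size) / 2) {
  m <- outer(seq_len(size), seq_len(size), function(rr, cc)
    (rr - center[1])^2 + (cc - center[2])^2 <= r^2)
  m + 0L
}

ellipse_mask <- function(H, W, a, b, theta_deg = 0,
                         center = c(H, W) / 2) {
  th <- theta_deg * pi / 180
  m <- outer(seq_len(H), seq_len(W), function(rr, cc) {
    u <- cos(th) * (cc - center[2]) + sin(th) * (rr - center[1])
    v <- -sin(th) * (cc - center[2]) + cos(th) * (rr - center[1])
    (u / a)^2 + (v / b)^2 <= 1
  })
  m + 0L
}

# small corpus of separable synthetic lesions: melanoma-like images are
# asymmetric and multi-colored, nevus-like images symmetric and uniform
make_corpus <- function(n_per_class, image_size = c(160, 200), seed0 = 1000) {
  mk <- function(i, melanoma) {
    make_lesion_image(synthetic_lesion_spec(
      image_size = image_size, seed = seed0 + i + 500 * melanoma,
      n_colors = if (melanoma) 3L else 1L,
      asymmetry_level = if (melanoma) 0.6 else 0,
      rotation = (i * 37) %% 180,
      semi_axes = round(image_size[1] * 0.18) + c(0, 3) + (i %% 5),
      hair_count = i %% 4, noise_sd = 2))$image
  }
  list(images = c(lapply(seq_len(n_per_class), mk, melanoma = TRUE),
                  lapply(seq_len(n_per_class), mk, melanoma = FALSE)),
       labels = rep(c(1L, 0L), each = n_per_class))
}

# build a roi_patch by hand from an RGB array and mask (for feature tests)
make_roi <- function(rgb, mask) {
  structure(list(rgb = rgb, lab = rgb_to_lab(rgb), mask = mask,
                 box = bounding_box(mask), sigma = NA_real_),
            class = "roi_patch")
}

# brute-force co-occurrence counting: loop over every pixel and offset in
# both directions
glcm_oracle <- function(gray, n_levels, offsets, mask = NULL) {
  H <- nrow(gray); W <- ncol(gray)
  counts <- matrix(0, n_levels, n_levels)
  for (off in offsets) for (r in seq_len(H)) for (c in seq_len(W)) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
    if (!is.null(mask) && (mask[r, c] != 1 || mask[r2, c2] != 1)) next
    i <- gray[r, c] + 1L; j <- gray[r2, c2] + 1L
    counts[i, j] <- counts[i, j] + 1
    counts[j, i] <- counts[j, i] + 1
  }
  counts / sum(counts)
}

# direct double-loop evaluation of the 13 texture statistics
haralick_oracle <- function(P) {
  Ng <- nrow(P)
  lg <- function(v) if (v > 0) log(v) else 0
  mu_x <- 0; mu_y <- 0
  for (i in 1:Ng) for (j in 1:Ng) { mu_x <- mu_x + i * P[i, j]
                                    mu_y <- mu_y + j * P[i, j] }
  vx <- 0; vy <- 0
  for (i in 1:Ng) for (j in 1:Ng) { vx <- vx + (i - mu_x)^2 * P[i, j]
                                    vy <- vy + (j - mu_y)^2 * P[i, j] }
  asm <- 0; con <- 0; cor <- 0; vari <- 0; idm <- 0; ent <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    p <- P[i, j]
    asm <- asm + p^2
    con <- con + (i - j)^2 * p
    cor <- cor + (i - mu_x) * (j - mu_y) * p
    vari <- vari + (i - mu_x)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    ent <- ent - p * lg(p)
  }
  cor <- if (vx > 0 && vy > 0) cor / sqrt(vx * vy) else 0
  ps <- numeric(2 * Ng)
  pd <- numeric(Ng)
  for (i in 1:Ng) for (j in 1:Ng) {
    ps[i + j] <- ps[i + j] + P[i, j]
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
  }
  sa <- 0; for (k in 2:(2 * Ng)) sa <- sa + k * ps[k]
  sv <- 0; for (k in 2:(2 * Ng)) sv <- sv + (k - sa)^2 * ps[k]
  se <- 0; for (k in 2:(2 * Ng)) se <- se - ps[k] * lg(ps[k])
  md <- 0; for (k in 0:(Ng - 1)) md <- md + k * pd[k + 1]
  dv <- 0; for (k in 0:(Ng - 1)) dv <- dv + (k - md)^2 * pd[k + 1]
  de <- 0; for (k in 0:(Ng - 1)) de <- de - pd[k + 1] * lg(pd[k + 1])
  px <- rowSums(P); py <- colSums(P)
  hx <- 0; for (i in 1:Ng) hx <- hx - px[i] * lg(px[i])
  hy <- 0; for (j in 1:Ng) hy <- hy - py[j] * lg(py[j])
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * lg(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  ic1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  ic2 <- min(max(1 - exp(-2 * (hxy2 - ent)), 0), 1)
  c(asm = asm, contrast = con, correlation = cor, variance = vari,
    idm = idm, entropy = ent, sum_average = sa, sum_variance = sv,
    sum_entropy = se, difference_variance = dv, difference_entropy = de,
    imcorr1 = ic1, imcorr2 = ic2)
}

# in-bounds majority vote, window by window
median_oracle <- function(mask, size) {
  r <- (size - 1) / 2
  H <- nrow(mask); W <- ncol(mask)
  out <- mask
  for (i in seq_len(H)) for (j in seq_len(W)) {
    rows <- max(1, i - r):min(H, i + r)
    cols <- max(1, j - r):min(W, j + r)
    v <- mask[rows, cols]
    out[i, j] <- (2 * sum(v) > length(v)) + 0L
  }
  out
}

# pixel-set symmetry oracle about a fixed axis: rasterize the reflection
# by scanning a generous pixel window and testing mirrored membership
symmetry_axis_oracle <- function(mask, theta, center) {
  H <- nrow(mask); W <- ncol(mask)
  e <- c(cos(theta), sin(theta))
  orig <- refl <- matrix(FALSE, 3 * H, 3 * W)  # offset by H, W
  for (r in seq_len(H)) for (c in seq_len(W))
    if (mask[r, c] == 1) orig[r + H, c + W] <- TRUE
  for (r in (-H):(2 * H)) for (c in (-W):(2 * W)) {
    u <- c - center[2]; v <- r - center[1]
    pr <- round(2 * (u * e[1] + v * e[2]) * e[2] - v + center[1])
    pc <- round(2 * (u * e[1] + v * e[2]) * e[1] - u + center[2])
    if (pr >= 1 && pr <= H && pc >= 1 && pc <= W && mask[pr, pc] == 1)
      refl[r + H, c + W] <- TRUE
  }
  inter <- sum(orig & refl)
  uni <- sum(orig | refl)
  fs <- sum(xor(orig, refl))
  1 - fs / uni
}
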