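#' Deep-feature extractor contract
#'
#' Pretrained CNN backbones are treated as frozen generic feature
#' extractors: a mapping from a resized ROI to a fixed-length nonnegative
#' vector (rectified global pooling of the last convolutional activations).
#' The package ships the contract, a registry of the standard backbone
#' output dimensions, and a deterministic random-filter surrogate so the
#' full pipeline runs and is testable without downloading any weights.
#'
#' @name deepfeat-module
NULL

#' Registry of CNN backbone feature dimensions
#'
#' Output dimensions of the penultimate (post-global-pool) layer of the
#' standard ImageNet-pretrained architectures.
#'
#' @return data.frame with columns `name` and `dim`.
#' @export
extractor_registry <- function() {
  data.frame(
    name = c("VGG19", "VGG16", "ResNET-50", "Inception v3", "Mobilenet v1",
             "Mobilenet v2", "DenseNET-201", "Xception"),
    dim = c(4096L, 4096L, 2048L, 2048L, 1024L, 1280L, 1920L, 2048L),
    stringsAsFactors = FALSE)
}

#' Construct a feature extractor
#'
#' @param name identifier.
#' @param dim declared output length.
#' @param input_size side length the ROI is resized to before extraction.
#' @param transform function mapping an `input_size` x `input_size` x 3
#'   array (values in \[0, 1\]) to a numeric vector of length `dim`.
#' @return object of class `feature_extractor`.
#' @export
feature_extractor <- function(name, dim, input_size, transform) {
  stopifnot(is.function(transform), dim >= 0)
  out <- list(name = name, dim = as.integer(dim),
              input_size = as.integer(input_size), transform = transform)
  class(out) <- "feature_extractor"
  out
}

#' @export
print.feature_extractor <- function(x, ...) {
  cat(sprintf("feature_extractor '%s': dim %d, input %dx%d\n",
              x$name, x$dim, x$input_size, x$input_size))
  invisible(x)
}

#' Look up a named CNN backbone
#'
#' Returns the extractor for one of the registry architectures. Actual
#' pretrained backbones are optional plugins: a `backend` function
#' (resized array -> vector) must be supplied by the caller, otherwise an
#' error names the missing backend. Use [surrogate_extractor()] for an
#' always-available deterministic stand-in.
#'
#' @param name one of `extractor_registry()$name`.
#' @param backend optional function implementing the backbone.
#' @param input_size input side length (default 224, the common backbone
#'   input).
#' @return a [feature_extractor()].
#' @export
deep_extractor <- function(name, backend = NULL, input_size = 224L) {
  reg <- extractor_registry()
  row <- reg[reg$name == name, ]
  if (nrow(row) == 0L)
    stop("unknown architecture '", name, "'; known: ",
         paste(reg$name, collapse = ", "))
  if (is.null(backend))
    stop("no backend available for '", name,
         "': supply a pretrained backbone function via `backend`, ",
         "or use surrogate_extractor()")
  feature_extractor(name, row$dim, input_size, backend)
}

#' Deterministic random-filter surrogate extractor
#'
#' A small fixed pipeline standing in for a pretrained backbone: `dim`
#' random 3 x 3 x 3 convolution filters (weights drawn once from `seed`),
#' rectification, and global average pooling. Deterministic per seed and
#' sensitive to image content, which is all the pipeline contract requires.
#'
#' @param seed integer seed for the filter weights.
#' @param dim number of filters = output length.
#' @param input_size side length the ROI is resized to (default 64).
#' @return a [feature_extractor()].
#' @export
surrogate_extractor <- function(seed = 1L, dim = 32L, input_size = 64L) {
  dim <- as.integer(dim)
  if (dim < 0L) stop("dim must be nonnegative")
  W <- with_local_seed(seed,
    matrix(rnorm(27L * dim), 27L, dim))
  transform <- function(x) {
    if (dim == 0L) return(numeric(0))
    s <- base::dim(x)[1]
    cols <- vector("list", 27L)
    q <- 1L
    for (ch in 1:3) for (dc in 0:2) for (dr in 0:2) {
      cols[[q]] <- as.vector(x[(1L + dr):(s - 2L + dr),
                               (1L + dc):(s - 2L + dc), ch])
      q <- q + 1L
    }
    patches <- do.call(cbind, cols)
    act <- pmax(patches %*% W, 0)     # rectifying pooling f(0, .)
    colMeans(act)
  }
  feature_extractor(sprintf("surrogate-%d", seed), dim, input_size, transform)
}

#' Extract deep features from an ROI
#'
#' Resizes the ROI crop to the extractor's input size (bilinear), scales
#' intensities to \[0, 1\], and applies the extractor transform.
#'
#' @param roi a `roi_patch` from [preprocess()].
#' @param ex a [feature_extractor()].
#' @return named numeric vector `deep_0 .. deep_{dim-1}` with attribute
#'   `extractor` carrying the extractor name.
#' @export
extract_deep <- function(roi, ex) {
  stopifnot(inherits(roi, "roi_patch"), inherits(ex, "feature_extractor"))
  if (ex$dim == 0L) {
    v <- numeric(0)
  } else {
    x <- EBImage::resize(roi$rgb / 255, w = ex$input_size, h = ex$input_size)
    x <- EBImage::imageData(x)
    v <- ex$transform(x)
    if (length(v) != ex$dim)
      stop(sprintf("extractor '%s' returned %d values, declared dim is %d",
                   ex$name, length(v), ex$dim))
    if (any(!is.finite(v))) stop("extractor produced non-finite values")
    names(v) <- sprintf("deep_%d", seq_len(ex$dim) - 1L)
  }
  attr(v, "extractor") <- ex$name
  v
}

#' Concatenate deep and handcrafted feature blocks
#'
#' Deep block first, then the 43 handcrafted slots; the fused vector has
#' length `dim + 43`.
#'
#' @param deep vector from [extract_deep()] (may have length 0).
#' @param hand vector from [handcraft_vector()].
#' @return named numeric vector.
#' @export
concat_features <- function(deep, hand) {
  if (any(!is.finite(deep)) || any(!is.finite(hand)))
    stop("feature blocks must be finite")
  out <- c(as.numeric(deep), as.numeric(hand))
  names(out) <- c(names(deep), names(hand))
  out
}
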