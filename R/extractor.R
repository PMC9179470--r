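#' Feature extractor configuration
#'
#' The extractor is a small MixNet-style stack: each block applies a mixed
#' depthwise convolution (MDConv) over its input channels, a pointwise
#' `1 x 1` convolution to the block's width, and a ReLU. Global average
#' pooling over the spatial dimensions turns the last block's channels into
#' a fixed-length feature vector, so the feature length equals the last
#' width regardless of input resolution.
#'
#' Channel groups are split contiguously; a block whose input has fewer
#' channels than requested groups falls back to fewer groups (a one-channel
#' input is a single group with the smallest kernel).
#'
#' @param blocks Number of blocks (default 3).
#' @param widths Output channels per block (default `c(16, 32, 64)`).
#' @param kernel_sizes Odd depthwise kernel sides shared by every block's
#'   groups (default `c(3, 5)`, i.e. two groups mixing two scales).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `extractor_config`.
#' @export
extractor_config <- function(blocks = 3L, widths = c(16L, 32L, 64L),
                             kernel_sizes = c(3L, 5L), seed = 1L) {
  check_number(blocks, "blocks", positive = TRUE, integer = TRUE)
  widths <- as.integer(widths)
  if (length(widths) != blocks || any(widths < 1L)) {
    abort("`widths` must supply one positive width per block.")
  }
  kernel_sizes <- as.integer(kernel_sizes)
  if (any(kernel_sizes < 3L) || any(kernel_sizes %% 2L == 0L)) {
    abort("`kernel_sizes` must be odd and at least 3.")
  }
  structure(list(blocks = as.integer(blocks), widths = widths,
                 kernel_sizes = kernel_sizes, seed = as.integer(seed)),
            class = "extractor_config")
}

# split M channels into at most length(kernel_sizes) near-equal groups
mdconv_spec_for <- function(M, kernel_sizes) {
  C <- min(length(kernel_sizes), M)
  base <- M %/% C
  groups <- rep(base, C)
  extra <- M - base * C
  if (extra > 0) groups[seq_len(extra)] <- groups[seq_len(extra)] + 1L
  mdconv_spec(M, groups, kernel_sizes[seq_len(C)])
}

#' Initialize extractor weights
#'
#' @param config An [extractor_config()].
#' @param in_channels Channels of the input images (1 for grayscale).
#' @return An object of class `feature_extractor` holding per-block MDConv
#'   kernels, pointwise weight matrices and biases.
#' @export
init_extractor <- function(config, in_channels = 1L) {
  stopifnot(inherits(config, "extractor_config"))
  check_number(in_channels, "in_channels", positive = TRUE, integer = TRUE)
  M <- as.integer(in_channels)
  layers <- vector("list", config$blocks)
  for (b in seq_len(config$blocks)) {
    spec <- mdconv_spec_for(M, config$kernel_sizes)
    width <- config$widths[b]
    seed_b <- derive_seed(config$seed, b)
    dw <- init_mdconv_weights(spec, seed = seed_b)
    pw <- with_seed(derive_seed(config$seed, 100L + b),
                    matrix(rnorm(width * M, sd = sqrt(2 / M)), width, M))
    layers[[b]] <- list(spec = spec, depthwise = dw, pointwise = pw,
                        bias = rep(0, width))
    M <- width
  }
  structure(list(config = config, in_channels = as.integer(in_channels),
                 layers = layers, out_length = M),
            class = "feature_extractor")
}

# forward one H x W x M stack through the blocks, return pooled vector
extractor_forward <- function(x, extractor) {
  for (layer in extractor$layers) {
    x <- mdconv_forward(x, layer$spec, layer$depthwise)
    H <- dim(x)[1]; W <- dim(x)[2]
    flat <- matrix(x, H * W, dim(x)[3])              # pixels x channels
    mixed <- flat %*% t(layer$pointwise)             # pixels x width
    mixed <- sweep(mixed, 2L, layer$bias, `+`)
    mixed[mixed < 0] <- 0                            # ReLU
    x <- array(mixed, c(H, W, ncol(mixed)))
  }
  colMeans(matrix(x, dim(x)[1] * dim(x)[2], dim(x)[3]))
}

#' Extract fixed-length feature vectors from a batch of images
#'
#' Runs each image through the extractor and global-average-pools the last
#' block. Deterministic for fixed weights; each image is processed
#' independently, so permuting the batch permutes the rows identically.
#'
#' @param images A list of equal-sized numeric matrices (grayscale planes),
#'   or a single matrix.
#' @param extractor A [init_extractor()] object.
#' @return A numeric matrix with one row per image and
#'   `extractor$out_length` columns, named `f1..fL`.
#' @export
extract_features <- function(images, extractor) {
  stopifnot(inherits(extractor, "feature_extractor"))
  if (is.matrix(images)) images <- list(images)
  if (length(images) == 0L) abort("`images` must be nonempty.")
  dims <- unique(lapply(images, dim))
  if (length(dims) != 1L) {
    abort("All images in a batch must share the same size.")
  }
  feats <- t(vapply(images, function(img) {
    check_matrix(img, "image")
    extractor_forward(array(img, c(dim(img), 1L)), extractor)
  }, numeric(extractor$out_length)))
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  feats
}
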