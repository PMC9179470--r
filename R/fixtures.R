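#' Synthetic eight-class texture dataset specification
#'
#' The default specification mirrors a benign/malignant histopathology
#' collection with four benign classes (A = adenosis, F = fibroadenoma,
#' PT = phyllodes tumor, TA = tubular adenoma; 106/237/115/130 images,
#' 588 total) and four malignant classes (DC = ductal, LC = lobular,
#' MC = mucinous, PC = papillary carcinoma; 788/137/169/138 images, 1232
#' total), 1820 images overall. Each class is a parametric texture family
#' — an oriented sinusoidal grating with class-specific frequency and
#' orientation plus a blob field of class-specific density — corrupted by
#' additive Gaussian pixel noise. The textures are a classification
#' *signal* with tunable difficulty, not a visual simulation of histology.
#'
#' @param counts Named integer vector of per-class image counts.
#' @param side Image side in pixels (square images; default 64).
#' @param sigma_noise Additive Gaussian noise standard deviation on the
#'   `[0, 1]` intensity scale (default 0.05).
#' @param seed Integer seed; the whole collection is a pure function of
#'   the spec.
#' @return An object of class `dataset_spec`.
#' @export
dataset_spec <- function(counts = c(A = 106L, F = 237L, PT = 115L,
                                    TA = 130L, DC = 788L, LC = 137L,
                                    MC = 169L, PC = 138L),
                         side = 64L, sigma_noise = 0.05, seed = 42L) {
  if (is.null(names(counts)) || any(names(counts) == "")) {
    abort("`counts` must be a named vector of class sizes.")
  }
  counts <- vapply(counts, function(x) {
    check_number(x, "counts", positive = TRUE, integer = TRUE)
    as.integer(x)
  }, integer(1))
  check_number(side, "side", positive = TRUE, integer = TRUE)
  if (side < 16L) abort("`side` must be at least 16 pixels.")
  if (sigma_noise < 0) abort("`sigma_noise` must be nonnegative.")
  structure(list(counts = counts, side = as.integer(side),
                 sigma_noise = sigma_noise, seed = as.integer(seed)),
            class = "dataset_spec")
}

#' Scale a dataset specification down
#'
#' Multiplies every class count by `scale` (flooring), keeping at least
#' `min_count` images per class so each class survives a stratified split.
#'
#' @param spec A [dataset_spec()].
#' @param scale Multiplier in (0, 1].
#' @param min_count Per-class floor (default 8).
#' @return A new `dataset_spec`.
#' @export
scale_dataset_spec <- function(spec, scale, min_count = 8L) {
  stopifnot(inherits(spec, "dataset_spec"))
  if (scale <= 0 || scale > 1) abort("`scale` must be in (0, 1].")
  counts <- pmax(as.integer(min_count), as.integer(floor(spec$counts * scale)))
  names(counts) <- names(spec$counts)
  dataset_spec(counts = counts, side = spec$side,
               sigma_noise = spec$sigma_noise, seed = spec$seed)
}

# per-class texture parameters: orientation (radians), grating frequency
# (cycles per image side), blob count and blob amplitude
class_texture_params <- function(class_names) {
  K <- length(class_names)
  tibble::tibble(
    class = class_names,
    theta = (seq_len(K) - 1) * pi / K,
    freq = 4 + 1.0 * (seq_len(K) - 1),
    n_blobs = 2L + 2L * (seq_len(K) - 1L),
    blob_amp = 0.25
  )
}

# one deterministic texture tile for class row `cp`
make_texture <- function(cp, side, sigma_noise, seed) {
  with_seed(seed, {
    xs <- matrix(seq_len(side), side, side, byrow = TRUE)
    ys <- matrix(seq_len(side), side, side)
    phase <- runif(1, 0, 2 * pi)
    carrier <- sin(2 * pi * cp$freq *
                     (xs * cos(cp$theta) + ys * sin(cp$theta)) / side + phase)
    img <- 0.5 + 0.22 * carrier
    if (cp$n_blobs > 0) {
      cx <- runif(cp$n_blobs, 1, side)
      cy <- runif(cp$n_blobs, 1, side)
      r <- runif(cp$n_blobs, side / 24, side / 10)
      for (bkt in seq_len(cp$n_blobs)) {
        img <- img + cp$blob_amp *
          exp(-((xs - cx[bkt])^2 + (ys - cy[bkt])^2) / (2 * r[bkt]^2))
      }
    }
    if (sigma_noise > 0) img <- img + rnorm(side * side, sd = sigma_noise)
    pmin(pmax(img, 0), 1)
  })
}

#' Generate the synthetic labeled image collection
#'
#' Produces every image deterministically from the spec seed; two calls
#' with the same spec yield identical pixels. Images can optionally be
#' written to `dir/<class>/<id>.png` as 8-bit grayscale PNG.
#'
#' @param spec A [dataset_spec()].
#' @param dir Optional output directory; created if missing.
#' @return A tibble manifest with columns `id`, `class` (factor in spec
#'   order), `image` (list of matrices) and, when written, `path`.
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "dataset_spec"))
  params <- class_texture_params(names(spec$counts))
  rows <- purrr::map(seq_along(spec$counts), function(k) {
    cls <- names(spec$counts)[k]
    cp <- params[k, ]
    purrr::map(seq_len(spec$counts[k]), function(j) {
      img_seed <- derive_seed(spec$seed, 1000L * k + j)
      img <- make_texture(cp, spec$side, spec$sigma_noise, img_seed)
      tibble::tibble(id = sprintf("%s_%04d", cls, j), class = cls,
                     image = list(img))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  rows$class <- factor(rows$class, levels = names(spec$counts))
  if (!is.null(dir)) {
    rows$path <- file.path(dir, as.character(rows$class),
                           paste0(rows$id, ".png"))
    for (d in unique(dirname(rows$path))) {
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
    }
    purrr::walk2(rows$image, rows$path, function(img, p)
      png::writePNG(img, p))
  }
  rows
}

#' Stratified train/validation/test split
#'
#' Splits a manifest per class into named fractions (which must sum to 1),
#' assigning each class's images by shuffled largest-remainder allocation
#' so observed proportions track the requested ones as closely as counts
#' allow. Reproducible given `seed`; the splits partition the manifest.
#'
#' @param manifest A tibble with a `class` column.
#' @param fractions Named positive fractions summing to 1, e.g.
#'   `c(train = 0.6, val = 0.2, test = 0.2)`.
#' @param seed Integer seed.
#' @return The manifest with an added `split` factor column.
#' @export
stratified_split <- function(manifest,
                             fractions = c(train = 0.6, val = 0.2,
                                           test = 0.2),
                             seed = 1L) {
  if (any(fractions <= 0)) abort("All split fractions must be positive.")
  if (abs(sum(fractions) - 1) > 1e-8) abort("`fractions` must sum to 1.")
  if (is.null(names(fractions))) {
    names(fractions) <- paste0("split", seq_along(fractions))
  }
  split_col <- character(nrow(manifest))
  with_seed(seed, {
    for (cls in unique(manifest$class)) {
      idx <- which(manifest$class == cls)
      n <- length(idx)
      alloc <- floor(n * fractions)
      rem <- n - sum(alloc)
      if (rem > 0) {
        top <- order(n * fractions - alloc, decreasing = TRUE)[seq_len(rem)]
        alloc[top] <- alloc[top] + 1L
      }
      lab <- rep(names(fractions), times = alloc)
      split_col[idx] <- sample(lab)
    }
  })
  manifest$split <- factor(split_col, levels = names(fractions))
  manifest
}
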