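#' Read one image file as a luminance matrix
#'
#' PNG is read with the png package, TIFF with the tiff package (if
#' installed). Multi-channel images are collapsed with [to_luminance()];
#' an alpha channel, if present, is dropped first.
#'
#' @param path Image file path.
#' @return A numeric matrix of intensities in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("Reading TIFF requires the tiff package.")
      }
      tiff::readTIFF(path)
    },
    abort(sprintf("Unsupported image format: .%s", ext))
  )
  if (is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 4L) {
    img <- img[, , 1:3, drop = FALSE]   # drop alpha
  }
  to_luminance(img)
}

#' Read a class-per-subdirectory image collection
#'
#' Each immediate subdirectory of `path` is a class label; images inside
#' are read in lexicographic order. Unreadable files are skipped with a
#' warning; empty class directories are excluded with a warning; other
#' file types are ignored.
#'
#' @param path Directory with one subdirectory per class.
#' @return A tibble manifest with `id`, `class` (factor, lexicographic
#'   levels), `image` (list of matrices) and `path`.
#' @export
read_image_dir <- function(path) {
  if (!dir.exists(path)) {
    abort(sprintf("Data directory does not exist: %s", path))
  }
  classes <- sort(list.dirs(path, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L) {
    abort(sprintf("No class subdirectories found under %s", path))
  }
  rows <- purrr::map(classes, function(cls) {
    files <- sort(list.files(file.path(path, cls),
                             pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) {
      warn(sprintf("Class directory `%s` has no images; excluded.", cls))
      return(NULL)
    }
    imgs <- purrr::map(files, function(f) {
      tryCatch(read_image(f), error = function(e) {
        warn(sprintf("Skipping unreadable image %s: %s", f,
                     conditionMessage(e)))
        NULL
      })
    })
    keep <- !vapply(imgs, is.null, logical(1))
    if (!any(keep)) return(NULL)
    tibble::tibble(id = tools::file_path_sans_ext(basename(files[keep])),
                   class = cls, image = imgs[keep], path = files[keep])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) abort("No readable images found.")
  out$class <- factor(out$class)
  out
}

#' Downscale an image by block mean pooling
#'
#' @param image Numeric matrix whose sides are divisible by `factor`.
#' @param factor Integer pooling factor (1 returns the input).
#' @return The pooled matrix.
#' @export
downscale_image <- function(image, factor = 2L) {
  check_matrix(image, "image")
  check_number(factor, "factor", positive = TRUE, integer = TRUE)
  if (factor == 1L) return(image)
  n <- nrow(image); m <- ncol(image)
  if (n %% factor != 0L || m %% factor != 0L) {
    abort("Image sides must be divisible by `factor`.")
  }
  rg <- (seq_len(n) - 1L) %/% factor
  cg <- (seq_len(m) - 1L) %/% factor
  acc <- rowsum(image, rg)
  acc <- t(rowsum(t(acc), cg))
  dimnames(acc) <- NULL
  acc / factor^2
}
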