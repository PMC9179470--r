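#' Gabor kernel parameters
#'
#' Bundles the five parameters of a two-dimensional Gabor filter: a complex
#' sinusoidal carrier of wavelength `delta` modulated by a Gaussian envelope
#' of standard deviation `sigma`, oriented at angle `theta`, with phase
#' offset `psi` and spatial aspect ratio `gamma`. When the half-response
#' spatial-frequency bandwidth `bw` (in octaves) is supplied, `sigma` is
#' derived from it via [sigma_from_bandwidth()] and any `sigma` argument is
#' ignored.
#'
#' Orientation is normalized into `[0, pi)`: a Gabor kernel at `theta + pi`
#' duplicates the response at `theta` up to carrier sign, so only the
#' half-turn range is meaningful.
#'
#' @param delta Carrier wavelength in pixels (> 0).
#' @param theta Orientation angle in radians; normalized into `[0, pi)`.
#' @param psi Phase offset in radians. `psi = 0` selects the even (real)
#'   component, `psi = pi/2` the odd (imaginary) component.
#' @param sigma Gaussian envelope standard deviation in pixels (> 0).
#'   Ignored when `bw` is given.
#' @param gamma Spatial aspect ratio (> 0); values below 1 elongate the
#'   envelope along the carrier direction.
#' @param bw Optional spatial-frequency bandwidth in octaves (> 0).
#' @return An object of class `gabor_params`.
#' @seealso [gabor_kernel()], [apply_gabor()], [gabor_denoise()]
#' @examples
#' gabor_params(delta = 4, theta = pi / 4, bw = 1)
#' @export
gabor_params <- function(delta, theta = 0, psi = 0, sigma = NULL,
                         gamma = 0.5, bw = NULL) {
  check_number(delta, "delta", positive = TRUE)
  check_number(theta, "theta")
  check_number(psi, "psi")
  check_number(gamma, "gamma", positive = TRUE)
  if (!is.null(bw)) {
    sigma <- sigma_from_bandwidth(delta, bw)
  } else if (is.null(sigma)) {
    abort("Supply either `sigma` or `bw`.")
  }
  check_number(sigma, "sigma", positive = TRUE)
  theta <- theta %% pi
  structure(
    list(delta = delta, theta = theta, psi = psi, sigma = sigma,
         gamma = gamma, bw = bw),
    class = "gabor_params"
  )
}

#' @export
print.gabor_params <- function(x, ...) {
  cat(sprintf(
    "<gabor_params> delta=%.4g theta=%.4g psi=%.4g sigma=%.4g gamma=%.4g%s\n",
    x$delta, x$theta, x$psi, x$sigma, x$gamma,
    if (is.null(x$bw)) "" else sprintf(" bw=%.4g", x$bw)
  ))
  invisible(x)
}

#' Envelope width from spatial-frequency bandwidth
#'
#' Converts a half-response spatial-frequency bandwidth `bw` (octaves) and
#' carrier wavelength `delta` into the Gaussian envelope standard deviation:
#' \deqn{\sigma = \frac{\delta}{\pi}\sqrt{\frac{\ln 2}{2}}\;
#'       \frac{2^{bw}+1}{2^{bw}-1}.}
#' The result is linear in `delta` and strictly decreasing in `bw`; as
#' `bw` grows the kernel approaches a single-cycle wavelet.
#'
#' @param delta Carrier wavelength in pixels (> 0).
#' @param bw Bandwidth in octaves (> 0; `bw = 0` is a pole of the formula).
#' @return Envelope standard deviation in pixels.
#' @examples
#' sigma_from_bandwidth(delta = pi, bw = 1) # = 3 * sqrt(log(2) / 2)
#' @export
sigma_from_bandwidth <- function(delta, bw) {
  check_number(delta, "delta", positive = TRUE)
  check_number(bw, "bw", positive = TRUE)
  (delta / pi) * sqrt(log(2) / 2) * (2^bw + 1) / (2^bw - 1)
}

#' Build a complex Gabor kernel
#'
#' Samples the Gabor function on the integer grid
#' `(-half_extent:half_extent)^2`. For offsets `(a, b)` (a: column/x,
#' b: row/y, y pointing down) the rotated coordinates are
#' `a' = a cos(theta) + b sin(theta)`, `b' = -a sin(theta) + b cos(theta)`
#' and the kernel value is
#' `exp(-(a'^2 + gamma^2 b'^2) / (2 sigma^2)) * exp(1i * (2 pi a' / delta + psi))`.
#' Matrix rows index `b`, columns index `a`, with the origin at the center.
#'
#' @param params A [gabor_params()] object.
#' @param half_extent Half support in pixels (>= 1); the kernel is a square
#'   of side `2 * half_extent + 1`. Defaults to `ceiling(3 * sigma)` so the
#'   envelope is covered to three standard deviations.
#' @return A complex matrix; `Re()` gives the even (`psi = 0`) filter.
#' @export
gabor_kernel <- function(params, half_extent = NULL) {
  stopifnot(inherits(params, "gabor_params"))
  if (is.null(half_extent)) half_extent <- max(1L, ceiling(3 * params$sigma))
  check_number(half_extent, "half_extent", integer = TRUE)
  if (half_extent < 1) abort("`half_extent` must be at least 1.")
  off <- seq(-half_extent, half_extent)
  a <- matrix(off, nrow = length(off), ncol = length(off), byrow = TRUE)
  b <- matrix(off, nrow = length(off), ncol = length(off))
  ap <- a * cos(params$theta) + b * sin(params$theta)
  bp <- -a * sin(params$theta) + b * cos(params$theta)
  env <- exp(-(ap^2 + params$gamma^2 * bp^2) / (2 * params$sigma^2))
  env * exp(1i * (2 * pi * ap / params$delta + params$psi))
}

# reflect-pad a matrix by `k` pixels on every side (no edge duplication)
pad_reflect <- function(x, k) {
  n <- nrow(x); m <- ncol(x)
  if (k >= n || k >= m) abort("Padding exceeds image size.")
  ridx <- c(seq(k + 1, 2), seq_len(n), seq(n - 1, n - k))
  cidx <- c(seq(k + 1, 2), seq_len(m), seq(m - 1, m - k))
  x[ridx, cidx, drop = FALSE]
}

# same-size 2-D convolution (true convolution: kernel flipped) with a choice
# of border rule; vectorized as a sum of shifted copies of the padded image
conv2_same <- function(image, kernel, border = c("reflect", "zero")) {
  border <- match.arg(border)
  k <- (nrow(kernel) - 1L) / 2L
  n <- nrow(image); m <- ncol(image)
  if (border == "reflect") {
    padded <- pad_reflect(image, k)
  } else {
    padded <- matrix(0, n + 2L * k, m + 2L * k)
    padded[(k + 1):(k + n), (k + 1):(k + m)] <- image
  }
  out <- matrix(0, n, m)
  for (dr in seq(-k, k)) {
    for (dc in seq(-k, k)) {
      w <- kernel[k + 1L + dr, k + 1L + dc]
      if (w == 0) next
      # convolution: output(r,c) += w * input(r - dr, c - dc)
      out <- out + w * padded[(k + 1 - dr):(k + n - dr),
                              (k + 1 - dc):(k + m - dc)]
    }
  }
  out
}

#' Filter an image plane with a Gabor kernel
#'
#' Convolves a grayscale image with the real part of the Gabor kernel
#' (true convolution, kernel flipped), returning an output of the same size.
#' Borders are handled by reflect padding by default, which avoids ringing
#' artifacts on small texture tiles. The operation is linear in the input.
#'
#' @param image Numeric matrix of pixel intensities (rows = y, top-left
#'   origin). Multi-channel arrays are first collapsed with [to_luminance()].
#' @param params A [gabor_params()] object.
#' @param half_extent Kernel half support; default `ceiling(3 * sigma)`.
#'   Must be smaller than the smaller image side.
#' @param border Border rule, `"reflect"` (default) or `"zero"`.
#' @return A numeric matrix the same size as `image`.
#' @export
apply_gabor <- function(image, params, half_extent = NULL,
                        border = c("reflect", "zero")) {
  if (is.array(image) && length(dim(image)) == 3L) image <- to_luminance(image)
  check_matrix(image, "image")
  stopifnot(inherits(params, "gabor_params"))
  if (is.null(half_extent)) half_extent <- max(1L, ceiling(3 * params$sigma))
  if (half_extent >= min(dim(image))) {
    abort("`half_extent` must be smaller than the smallest image side.")
  }
  kern <- Re(gabor_kernel(params, half_extent))
  conv2_same(image, kern, border = match.arg(border))
}

#' Collapse a color image to one luminance plane
#'
#' Channels are averaged with equal weight; the pipeline treats texture, not
#' color, as the discriminative signal, so an unweighted mean is the simplest
#' reproducible rule.
#'
#' @param image A numeric `H x W x C` array or an `H x W` matrix (returned
#'   unchanged).
#' @return An `H x W` numeric matrix.
#' @export
to_luminance <- function(image) {
  if (is.matrix(image)) return(image)
  if (!is.array(image) || length(dim(image)) != 3L) {
    abort("`image` must be a matrix or an H x W x C array.")
  }
  apply(image, c(1, 2), mean)
}

#' Gabor filter-bank denoising stage
#'
#' The pipeline's preprocessing step: the image is filtered with a small
#' bank of even (`psi = 0`) Gabor kernels at several orientations and the
#' responses are averaged into a single smoothed plane. With the default
#' four orientations the bank acts as an orientation-agnostic band-pass
#' smoother that suppresses pixel noise while retaining the texture band
#' around the carrier wavelength.
#'
#' `gf_preprocess()` is an alias: the pipeline stage is conventionally
#' called "GF" (Gaussian filtering) after the Gaussian envelope of the
#' kernels, although the kernels themselves are Gabor filters.
#'
#' @param image Numeric matrix (or `H x W x C` array, collapsed first).
#' @param delta Carrier wavelength in pixels.
#' @param orientations Vector of orientation angles in radians.
#' @param psi,gamma,bw Remaining kernel parameters; see [gabor_params()].
#' @param half_extent Kernel half support; default `ceiling(3 * sigma)`.
#' @return A numeric matrix the same size as the input plane.
#' @export
gabor_denoise <- function(image, delta = 4,
                          orientations = c(0, pi / 4, pi / 2, 3 * pi / 4),
                          psi = 0, gamma = 0.5, bw = 1, half_extent = NULL) {
  if (is.array(image) && length(dim(image)) == 3L) image <- to_luminance(image)
  check_matrix(image, "image")
  resp <- lapply(orientations, function(th) {
    p <- gabor_params(delta = delta, theta = th, psi = psi, gamma = gamma,
                      bw = bw)
    apply_gabor(image, p, half_extent = half_extent)
  })
  Reduce(`+`, resp) / length(resp)
}

#' @rdname gabor_denoise
#' @export
gf_preprocess <- gabor_denoise
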