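#' Convolution size specification
#'
#' Describes one convolutional layer for parameter and multiply counting:
#' square kernel side `Dk`, `M` input channels, `N` output channels and an
#' output feature map of side `DF`.
#'
#' @param Dk Kernel side in pixels (integer >= 1).
#' @param M Input channels (integer >= 1).
#' @param N Output channels (integer >= 1).
#' @param DF Output feature-map side in pixels (integer >= 1).
#' @return An object of class `conv_spec`.
#' @seealso [standard_conv_params()], [dsc_params()], [conv_costs()]
#' @export
conv_spec <- function(Dk, M, N, DF = 1L) {
  for (nm in c("Dk", "M", "N", "DF")) {
    check_number(get(nm), nm, positive = TRUE, integer = TRUE)
  }
  structure(list(Dk = as.integer(Dk), M = as.integer(M),
                 N = as.integer(N), DF = as.integer(DF)),
            class = "conv_spec")
}

#' Parameter count of a standard convolution
#'
#' A dense convolution mixing all `M` input channels into each of `N`
#' output channels with a `Dk x Dk` kernel carries `Dk^2 * M * N` weights.
#'
#' @param spec A [conv_spec()].
#' @return Integer-valued parameter count.
#' @examples
#' standard_conv_params(conv_spec(3, 16, 32)) # 4608
#' @export
standard_conv_params <- function(spec) {
  stopifnot(inherits(spec, "conv_spec"))
  with(spec, Dk * Dk * M * N)
}

#' Parameter count of a depthwise separable convolution
#'
#' The factorized form filters each channel with its own `Dk x Dk` kernel
#' (`Dk^2 * M` weights) and then mixes channels with a pointwise `1 x 1`
#' convolution (`M * N` weights), totalling `Dk^2 * M + M * N`. This is
#' smaller than the standard count whenever `Dk^2 * N > Dk^2 + N`.
#'
#' @param spec A [conv_spec()].
#' @return Integer-valued parameter count.
#' @examples
#' dsc_params(conv_spec(3, 16, 32)) # 656
#' @export
dsc_params <- function(spec) {
  stopifnot(inherits(spec, "conv_spec"))
  with(spec, Dk * Dk * M + M * N)   # 1 x 1 pointwise contributes M * N
}

#' Multiply counts and cost ratio of standard vs. separable convolution
#'
#' Over a `DF x DF` output map the standard convolution performs
#' `Dk^2 * M * N * DF^2` multiplies and the depthwise separable form
#' `Dk^2 * M * DF^2 + M * N * DF^2`. Their ratio collapses to the
#' closed form `1/N + 1/Dk^2`, independent of `M` and `DF`; separable
#' convolution is cheaper exactly when that ratio is below 1.
#'
#' @param spec A [conv_spec()].
#' @return A one-row tibble with columns `standard`, `dsc` and `ratio`.
#' @examples
#' conv_costs(conv_spec(3, 16, 32, DF = 8))
#' @export
conv_costs <- function(spec) {
  stopifnot(inherits(spec, "conv_spec"))
  standard <- with(spec, Dk^2 * M * N * DF^2)
  dsc <- with(spec, Dk^2 * M * DF^2 + M * N * DF^2)
  tibble::tibble(standard = standard, dsc = dsc, ratio = dsc / standard)
}

#' Mixed depthwise convolution specification
#'
#' MDConv partitions the `M` input channels into `C` contiguous groups and
#' filters each group depthwise with its own (odd, >= 3) kernel size, so a
#' single layer sees several receptive-field scales at depthwise cost.
#' With `C = 1` it reduces to a plain depthwise convolution.
#'
#' @param M Total input channels.
#' @param groups Integer vector of `C` group sizes summing to `M`.
#' @param kernel_sizes Integer vector of `C` odd kernel sides (>= 3).
#' @return An object of class `mdconv_spec`.
#' @export
mdconv_spec <- function(M, groups, kernel_sizes) {
  check_number(M, "M", positive = TRUE, integer = TRUE)
  groups <- as.integer(groups)
  kernel_sizes <- as.integer(kernel_sizes)
  if (length(groups) < 1L || length(groups) != length(kernel_sizes)) {
    abort("`groups` and `kernel_sizes` must have equal positive length.")
  }
  if (any(groups < 1L) || sum(groups) != M) {
    abort("`groups` must be positive and sum to `M`.")
  }
  if (any(kernel_sizes < 3L) || any(kernel_sizes %% 2L == 0L)) {
    abort("`kernel_sizes` must be odd and at least 3.")
  }
  structure(list(M = as.integer(M), groups = groups,
                 kernel_sizes = kernel_sizes),
            class = "mdconv_spec")
}

#' Initialize depthwise kernels for an MDConv layer
#'
#' One `k x k` kernel per channel, grouped per the spec, drawn from a
#' scaled normal (He-style, variance `2 / k^2`).
#'
#' @param spec An [mdconv_spec()].
#' @param seed Integer RNG seed.
#' @return A list with one element per group; each element a list of
#'   per-channel kernel matrices.
#' @export
init_mdconv_weights <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "mdconv_spec"))
  with_seed(seed, {
    purrr::map2(spec$groups, spec$kernel_sizes, function(g, k) {
      purrr::map(seq_len(g), function(.)
        matrix(rnorm(k * k, sd = sqrt(2 / (k * k))), k, k))
    })
  })
}

#' Mixed depthwise convolution forward pass
#'
#' Channels are split contiguously by `spec$groups`; each channel is
#' convolved (true convolution, same padding, stride 1) with its group's
#' kernel. Channel order is preserved.
#'
#' @param x An `H x W x M` numeric array of feature maps.
#' @param spec An [mdconv_spec()]; `spec$M` must equal `dim(x)[3]`.
#' @param weights Kernels as produced by [init_mdconv_weights()].
#' @param border Border rule passed to the convolution (`"zero"` default
#'   for feature maps).
#' @return An `H x W x M` numeric array.
#' @export
mdconv_forward <- function(x, spec, weights, border = "zero") {
  stopifnot(inherits(spec, "mdconv_spec"))
  if (!is.array(x) || length(dim(x)) != 3L) {
    abort("`x` must be an H x W x M array.")
  }
  if (dim(x)[3] != spec$M) {
    abort(sprintf("`x` has %d channels but spec declares M = %d.",
                  dim(x)[3], spec$M))
  }
  if (length(weights) != length(spec$groups) ||
      !all(lengths(weights) == spec$groups)) {
    abort("`weights` do not match the group structure of `spec`.")
  }
  out <- array(0, dim(x))
  ch <- 0L
  for (g in seq_along(spec$groups)) {
    for (j in seq_len(spec$groups[g])) {
      ch <- ch + 1L
      out[, , ch] <- conv2_same(x[, , ch], weights[[g]][[j]], border = border)
    }
  }
  out
}
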