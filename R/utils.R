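#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data
#' @importFrom stats runif rnorm predict
#' @importFrom utils head tail
NULL

# round half away from zero at `digits`; base round() is half-to-even
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

check_number <- function(x, name, positive = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be strictly positive.", name))
  }
  if (integer && x != as.integer(x)) {
    abort(sprintf("`%s` must be a whole number.", name))
  }
  invisible(x)
}

check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x) || length(x) == 0L) {
    abort(sprintf("`%s` must be a nonempty numeric matrix.", name))
  }
  if (!all(is.finite(x))) {
    abort(sprintf("`%s` must contain finite values only.", name))
  }
  invisible(x)
}

# deterministic child seeds so each pipeline stage has its own stream
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483647L
}

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
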