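#' GRU layer parameters
#'
#' Weight container for one gated recurrent unit layer: recurrent matrices
#' `Wu`, `Wr`, `Wc` (hidden x hidden), input matrices `Uu`, `Ur`, `Uc`
#' (hidden x input) and biases `bu`, `br`, `bc` for the update gate, reset
#' gate and candidate state respectively.
#'
#' @param input_size Input dimension of the layer.
#' @param hidden_size Hidden state dimension.
#' @param seed Integer seed for the uniform initialization.
#' @param scale Half-width of the uniform init range (default
#'   `1/sqrt(hidden_size)`).
#' @return An object of class `gru_layer`.
#' @export
gru_layer_params <- function(input_size, hidden_size, seed = 1L,
                             scale = NULL) {
  check_number(input_size, "input_size", positive = TRUE, integer = TRUE)
  check_number(hidden_size, "hidden_size", positive = TRUE, integer = TRUE)
  if (is.null(scale)) scale <- 1 / sqrt(hidden_size)
  h <- hidden_size; d <- input_size
  with_seed(seed, {
    rw <- function(nr, nc) matrix(runif(nr * nc, -scale, scale), nr, nc)
    structure(list(
      Wu = rw(h, h), Wr = rw(h, h), Wc = rw(h, h),
      Uu = rw(h, d), Ur = rw(h, d), Uc = rw(h, d),
      bu = rep(0, h), br = rep(0, h), bc = rep(0, h)
    ), class = "gru_layer")
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One GRU cell step
#'
#' Computes the update gate `u = sigma(Wu h + Uu x + bu)`, reset gate
#' `r = sigma(Wr h + Ur x + br)`, candidate
#' `c = tanh(Wc (r * h) + Uc x + bc)` and the new hidden state
#' `h' = u * c + (1 - u) * h`, where `*` is elementwise and `h` the
#' previous hidden state. Gates lie strictly in (0, 1) and the candidate in
#' (-1, 1) for finite inputs.
#'
#' @param x Input vector (layer input at this time step).
#' @param h_prev Previous hidden state vector.
#' @param params A [gru_layer_params()] object.
#' @return A list with `u`, `r`, `candidate` and `h` (the new state).
#' @export
gru_cell_step <- function(x, h_prev, params) {
  stopifnot(inherits(params, "gru_layer"))
  if (length(x) != ncol(params$Uu)) {
    abort(sprintf("Input length %d does not match layer input size %d.",
                  length(x), ncol(params$Uu)))
  }
  if (length(h_prev) != nrow(params$Wu)) {
    abort(sprintf("Hidden length %d does not match layer hidden size %d.",
                  length(h_prev), nrow(params$Wu)))
  }
  u <- sigmoid(drop(params$Wu %*% h_prev + params$Uu %*% x) + params$bu)
  r <- sigmoid(drop(params$Wr %*% h_prev + params$Ur %*% x) + params$br)
  candidate <- tanh(drop(params$Wc %*% (r * h_prev) + params$Uc %*% x) +
                      params$bc)
  h <- u * candidate + (1 - u) * h_prev
  list(u = u, r = r, candidate = candidate, h = h)
}

#' Chunk a feature vector into a GRU input sequence
#'
#' Deterministically partitions a feature vector into `length(x) / chunk`
#' equal consecutive sub-vectors, presented to the recurrent stack as time
#' steps in index order. Concatenating the rows reproduces the input.
#'
#' @param x Numeric feature vector; its length must be divisible by
#'   `chunk`.
#' @param chunk Sub-vector length (<= `length(x)`).
#' @return A `t x chunk` matrix whose rows are the time steps.
#' @export
featuremap_to_sequence <- function(x, chunk) {
  x <- as.numeric(x)
  check_number(chunk, "chunk", positive = TRUE, integer = TRUE)
  if (chunk > length(x)) abort("`chunk` exceeds the feature length.")
  if (length(x) %% chunk != 0L) {
    abort("Feature length must be divisible by `chunk`.")
  }
  matrix(x, ncol = chunk, byrow = TRUE)
}

#' Stacked GRU forward pass
#'
#' Runs the input sequence through a stack of GRU layers: layer 1 consumes
#' the embedding sequence, each higher layer consumes the hidden states of
#' the layer below at the same time step. All initial hidden states are
#' zero. The top layer's final hidden state is mapped through an affine
#' head and a softmax into class probabilities.
#'
#' @param sequence A `t x d` matrix of time-step inputs (rows in order), or
#'   a vector for a single step.
#' @param stack A list of [gru_layer_params()], bottom first.
#' @param head A list with `W` (K x hidden) and `b` (length K) for the
#'   softmax class layer.
#' @param dropout Optional dropout rate applied to inter-layer hidden
#'   states during training; `keep_masks` of matching shape must then be
#'   supplied by the training loop. Inference leaves this at 0.
#' @param masks Internal: pre-drawn inverted-dropout masks.
#' @param details If `TRUE`, also return all hidden states and gate values
#'   (used by the training backward pass).
#' @return A probability vector of length `K` summing to 1 (or a list with
#'   `probs` and the cached forward quantities when `details = TRUE`).
#' @export
sgru_forward <- function(sequence, stack, head, dropout = 0, masks = NULL,
                         details = FALSE) {
  if (is.vector(sequence) && is.numeric(sequence)) {
    sequence <- matrix(sequence, nrow = 1L)
  }
  if (!is.matrix(sequence) || nrow(sequence) == 0L) {
    abort("`sequence` must be a nonempty t x d matrix.")
  }
  if (length(stack) < 1L) abort("`stack` needs at least one layer.")
  tlen <- nrow(sequence)
  L <- length(stack)
  cache <- vector("list", L)
  inputs <- sequence
  for (l in seq_len(L)) {
    h <- rep(0, nrow(stack[[l]]$Wu))
    steps <- vector("list", tlen)
    outs <- matrix(0, tlen, length(h))
    for (tt in seq_len(tlen)) {
      st <- gru_cell_step(inputs[tt, ], h, stack[[l]])
      steps[[tt]] <- c(st, list(h_prev = h, x = inputs[tt, ]))
      h <- st$h
      outs[tt, ] <- h
    }
    cache[[l]] <- list(steps = steps, outs = outs)
    inputs <- outs
    if (l < L && dropout > 0) {
      m <- if (is.null(masks)) {
        matrix(1, tlen, ncol(outs))
      } else {
        masks[[l]]
      }
      inputs <- inputs * m
      cache[[l]]$mask <- m
    }
  }
  top <- inputs[tlen, ]
  logits <- drop(head$W %*% top) + head$b
  z <- logits - max(logits)
  probs <- exp(z) / sum(exp(z))
  if (!details) return(probs)
  list(probs = probs, cache = cache, top = top, logits = logits)
}
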