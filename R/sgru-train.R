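# backward pass through one GRU layer for one sample; returns input grads
# and accumulates parameter grads into `acc` (an environment slot list)
gru_layer_backward <- function(layer_cache, params, douts) {
  tlen <- nrow(douts)
  h <- ncol(douts)
  g <- list(Wu = 0 * params$Wu, Wr = 0 * params$Wr, Wc = 0 * params$Wc,
            Uu = 0 * params$Uu, Ur = 0 * params$Ur, Uc = 0 * params$Uc,
            bu = 0 * params$bu, br = 0 * params$br, bc = 0 * params$bc)
  dxs <- matrix(0, tlen, ncol(params$Uu))
  dh_carry <- rep(0, h)
  for (tt in seq(tlen, 1L)) {
    st <- layer_cache$steps[[tt]]
    dh <- douts[tt, ] + dh_carry
    du <- dh * (st$candidate - st$h_prev)
    dc <- dh * st$u
    dh_prev <- dh * (1 - st$u)
    dc_pre <- dc * (1 - st$candidate^2)
    rh <- st$r * st$h_prev
    g$Wc <- g$Wc + tcrossprod(dc_pre, rh)
    g$Uc <- g$Uc + tcrossprod(dc_pre, st$x)
    g$bc <- g$bc + dc_pre
    ds <- drop(crossprod(params$Wc, dc_pre))
    dr <- ds * st$h_prev
    dh_prev <- dh_prev + ds * st$r
    du_pre <- du * st$u * (1 - st$u)
    dr_pre <- dr * st$r * (1 - st$r)
    g$Wu <- g$Wu + tcrossprod(du_pre, st$h_prev)
    g$Uu <- g$Uu + tcrossprod(du_pre, st$x)
    g$bu <- g$bu + du_pre
    g$Wr <- g$Wr + tcrossprod(dr_pre, st$h_prev)
    g$Ur <- g$Ur + tcrossprod(dr_pre, st$x)
    g$br <- g$br + dr_pre
    dh_carry <- dh_prev + drop(crossprod(params$Wu, du_pre)) +
      drop(crossprod(params$Wr, dr_pre))
    dxs[tt, ] <- drop(crossprod(params$Uu, du_pre)) +
      drop(crossprod(params$Ur, dr_pre)) + drop(crossprod(params$Uc, dc_pre))
  }
  list(grads = g, dxs = dxs)
}

# full backward for one sample given the detailed forward cache
sgru_backward <- function(fwd, stack, head, y_index) {
  K <- length(fwd$probs)
  dlogits <- fwd$probs
  dlogits[y_index] <- dlogits[y_index] - 1
  gheadW <- tcrossprod(dlogits, fwd$top)
  gheadb <- dlogits
  L <- length(stack)
  tlen <- nrow(fwd$cache[[1]]$outs)
  douts <- matrix(0, tlen, length(fwd$top))
  dtop <- drop(crossprod(head$W, dlogits))
  # the top hidden state at the final step feeds the head
  douts[tlen, ] <- dtop
  layer_grads <- vector("list", L)
  for (l in seq(L, 1L)) {
    bk <- gru_layer_backward(fwd$cache[[l]], stack[[l]], douts)
    layer_grads[[l]] <- bk$grads
    if (l > 1L) {
      douts <- bk$dxs
      m <- fwd$cache[[l - 1L]]$mask
      if (!is.null(m)) douts <- douts * m
    }
  }
  list(layers = layer_grads, head = list(W = gheadW, b = gheadb))
}

init_sgru <- function(input_size, hidden_size, n_layers, K, seed) {
  stack <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    d <- if (l == 1L) input_size else hidden_size
    stack[[l]] <- gru_layer_params(d, hidden_size,
                                   seed = derive_seed(seed, 200L + l))
  }
  scale <- 1 / sqrt(hidden_size)
  head <- with_seed(derive_seed(seed, 300L), list(
    W = matrix(runif(K * hidden_size, -scale, scale), K, hidden_size),
    b = rep(0, K)
  ))
  list(stack = stack, head = head)
}

model_accuracy <- function(model, sequences, y_idx) {
  pred <- vapply(sequences, function(s)
    which.max(sgru_forward(s, model$stack, model$head)), integer(1))
  mean(pred == y_idx)
}

#' Train the stacked GRU classification head
#'
#' Minimizes multinomial cross-entropy over the training features by plain
#' mini-batch stochastic gradient descent. Each feature vector is chunked
#' into a short sequence ([featuremap_to_sequence()]); inverted dropout is
#' applied to inter-layer hidden states during training only. All
#' randomness (initialization, shuffling, dropout masks) derives from
#' `seed`, so two runs with the same seed produce identical parameters.
#'
#' @param x_train,x_val Numeric feature matrices (rows = samples).
#' @param y_train,y_val Class labels (factor or character/integer).
#' @param hyper Named list of hyperparameters; recognized entries with
#'   defaults: `learning_rate = 0.01`, `dropout = 0.5`, `batch_size = 5`,
#'   `hidden_size = 16`, `layers = 2`, `epochs = 50`, `steps = 4` (number
#'   of time steps the feature vector is chunked into; must divide the
#'   feature length, otherwise a single step is used).
#' @param seed Integer RNG seed.
#' @return An object of class `sgru_fit` with the trained `stack`, `head`,
#'   the chunk size, class levels and a per-epoch `history` tibble of
#'   train/validation accuracy and loss.
#' @export
train_classifier <- function(x_train, y_train, x_val = NULL, y_val = NULL,
                             hyper = list(), seed = 1L) {
  if (!is.matrix(x_train) || nrow(x_train) == 0L) {
    abort("`x_train` must be a nonempty feature matrix.")
  }
  if (nrow(x_train) != length(y_train)) {
    abort("`x_train` and `y_train` sizes disagree.")
  }
  defaults <- list(learning_rate = 0.01, dropout = 0.5, batch_size = 5L,
                   hidden_size = 16L, layers = 2L, epochs = 50L, steps = 4L)
  hyper <- utils::modifyList(defaults, hyper[!vapply(hyper, is.null, TRUE)])
  hyper$batch_size <- max(1L, as.integer(round(hyper$batch_size)))
  hyper$hidden_size <- max(1L, as.integer(round(hyper$hidden_size)))
  hyper$layers <- max(1L, as.integer(round(hyper$layers)))
  hyper$epochs <- as.integer(hyper$epochs)
  if (hyper$epochs < 0L) abort("`epochs` must be nonnegative.")

  classes <- sort(unique(as.character(y_train)))
  if (is.factor(y_train)) classes <- levels(y_train)
  y_idx <- match(as.character(y_train), classes)
  K <- length(classes)
  p <- ncol(x_train)
  # z-score features on the training set; the same affine map is stored in
  # the fit and applied at prediction time
  center <- colMeans(x_train)
  scale <- apply(x_train, 2L, stats::sd)
  scale[scale < 1e-8] <- 1
  x_train <- sweep(sweep(x_train, 2L, center), 2L, scale, `/`)
  if (!is.null(x_val)) {
    x_val <- sweep(sweep(x_val, 2L, center), 2L, scale, `/`)
  }
  chunk <- if (p %% hyper$steps == 0L) p %/% hyper$steps else p
  seqs <- lapply(seq_len(nrow(x_train)), function(i)
    featuremap_to_sequence(x_train[i, ], chunk))
  tlen <- nrow(seqs[[1]])

  has_val <- !is.null(x_val) && nrow(x_val) > 0L
  if (has_val) {
    yv_idx <- match(as.character(y_val), classes)
    vseqs <- lapply(seq_len(nrow(x_val)), function(i)
      featuremap_to_sequence(x_val[i, ], chunk))
  }

  model <- init_sgru(chunk, hyper$hidden_size, hyper$layers, K, seed)
  n <- nrow(x_train)
  history <- vector("list", hyper$epochs)

  if (hyper$epochs > 0L) with_seed(derive_seed(seed, 400L), {
    for (ep in seq_len(hyper$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = hyper$batch_size)) {
        idx <- ord[start:min(start + hyper$batch_size - 1L, n)]
        acc <- NULL
        for (i in idx) {
          masks <- NULL
          if (hyper$dropout > 0 && hyper$layers > 1L) {
            keep <- 1 - hyper$dropout
            masks <- lapply(seq_len(hyper$layers - 1L), function(.)
              matrix(rbinom(tlen * hyper$hidden_size, 1L, keep) / keep,
                     tlen, hyper$hidden_size))
          }
          fwd <- sgru_forward(seqs[[i]], model$stack, model$head,
                              dropout = hyper$dropout, masks = masks,
                              details = TRUE)
          ep_loss <- ep_loss - log(max(fwd$probs[y_idx[i]], 1e-12))
          bk <- sgru_backward(fwd, model$stack, model$head, y_idx[i])
          if (is.null(acc)) {
            acc <- bk
          } else {
            for (l in seq_along(acc$layers)) {
              acc$layers[[l]] <- purrr::map2(acc$layers[[l]], bk$layers[[l]], `+`)
            }
            acc$head$W <- acc$head$W + bk$head$W
            acc$head$b <- acc$head$b + bk$head$b
          }
        }
        lr <- hyper$learning_rate / length(idx)
        for (l in seq_along(model$stack)) {
          for (nm in names(acc$layers[[l]])) {
            model$stack[[l]][[nm]] <- model$stack[[l]][[nm]] -
              lr * acc$layers[[l]][[nm]]
          }
        }
        model$head$W <- model$head$W - lr * acc$head$W
        model$head$b <- model$head$b - lr * acc$head$b
      }
      history[[ep]] <- tibble::tibble(
        epoch = ep,
        train_loss = ep_loss / n,
        train_accuracy = model_accuracy(model, seqs, y_idx),
        val_accuracy = if (has_val) model_accuracy(model, vseqs, yv_idx)
                       else NA_real_
      )
    }
  })

  structure(list(
    stack = model$stack, head = model$head, chunk = chunk,
    classes = classes, hyper = hyper, seed = as.integer(seed),
    center = center, scale = scale,
    history = if (hyper$epochs > 0L) dplyr::bind_rows(history)
              else tibble::tibble(epoch = integer(), train_loss = double(),
                                  train_accuracy = double(),
                                  val_accuracy = double())
  ), class = "sgru_fit")
}

#' Predict classes and probabilities from a fitted stacked GRU
#'
#' @param object An `sgru_fit`.
#' @param newdata Feature matrix with the training feature length.
#' @param ... Unused.
#' @return A tibble with `.pred_class` and one `.prob_<class>` column per
#'   class.
#' @export
predict.sgru_fit <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- rbind(newdata)
  newdata <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, `/`)
  probs <- t(vapply(seq_len(nrow(newdata)), function(i) {
    s <- featuremap_to_sequence(newdata[i, ], object$chunk)
    sgru_forward(s, object$stack, object$head)
  }, numeric(length(object$classes))))
  colnames(probs) <- paste0(".prob_", object$classes)
  out <- tibble::as_tibble(probs)
  out$.pred_class <- factor(object$classes[max.col(probs, ties.method = "first")],
                            levels = object$classes)
  dplyr::relocate(out, ".pred_class")
}

#' @export
print.sgru_fit <- function(x, ...) {
  cat(sprintf(
    "<sgru_fit> %d layer(s), hidden %d, %d classes, chunk %d, %d epoch(s)\n",
    x$hyper$layers, x$hyper$hidden_size, length(x$classes), x$chunk,
    x$hyper$epochs))
  if (nrow(x$history) > 0) {
    last <- tail(x$history, 1)
    cat(sprintf("  final train accuracy %.3f%s\n", last$train_accuracy,
                if (is.na(last$val_accuracy)) "" else
                  sprintf(", val accuracy %.3f", last$val_accuracy)))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a stacked GRU fit
#' @param x An `sgru_fit`.
#' @param ... Unused.
#' @return The history tibble (epoch, train loss, train/val accuracy).
#' @method tidy sgru_fit
#' @export
tidy.sgru_fit <- function(x, ...) x$history

#' One-row summary of a stacked GRU fit
#' @param x An `sgru_fit`.
#' @param ... Unused.
#' @method glance sgru_fit
#' @export
glance.sgru_fit <- function(x, ...) {
  last <- if (nrow(x$history) > 0) tail(x$history, 1) else
    tibble::tibble(train_loss = NA_real_, train_accuracy = NA_real_,
                   val_accuracy = NA_real_)
  tibble::tibble(
    layers = x$hyper$layers, hidden_size = x$hyper$hidden_size,
    epochs = x$hyper$epochs, classes = length(x$classes),
    train_loss = last$train_loss, train_accuracy = last$train_accuracy,
    val_accuracy = last$val_accuracy
  )
}
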