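#' Declare a hyperparameter search space
#'
#' Each dimension is a named list entry with `lower`, `upper` and a `type`:
#' `"continuous"`, `"integer"` (positions are rounded and clamped) or
#' `"log"` (the position interpolates in log space, e.g. for learning
#' rates). The default space covers the classifier hyperparameters the
#' optimizer tunes: learning rate (log scale), dropout, batch size and
#' GRU hidden size.
#'
#' @param ... Named dimensions, each `list(lower =, upper =, type =)`.
#' @return An object of class `tune_space`.
#' @export
tune_space <- function(...) {
  dims <- list(...)
  if (length(dims) == 0L) {
    dims <- list(
      learning_rate = list(lower = 1e-3, upper = 1e-1, type = "log"),
      dropout = list(lower = 0, upper = 0.8, type = "continuous"),
      batch_size = list(lower = 2, upper = 16, type = "integer"),
      hidden_size = list(lower = 4, upper = 32, type = "integer")
    )
  }
  if (is.null(names(dims)) || any(names(dims) == "")) {
    abort("Every tuning dimension must be named.")
  }
  for (nm in names(dims)) {
    d <- dims[[nm]]
    if (!all(c("lower", "upper") %in% names(d))) {
      abort(sprintf("Dimension `%s` needs `lower` and `upper`.", nm))
    }
    if (d$lower > d$upper) {
      abort(sprintf("Dimension `%s` has lower > upper.", nm))
    }
    dims[[nm]]$type <- match.arg(d$type %||% "continuous",
                                 c("continuous", "integer", "log"))
  }
  structure(dims, class = "tune_space")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal continuous bounds in which the optimizer works
space_bounds <- function(space) {
  lower <- vapply(space, function(d)
    if (d$type == "log") log(d$lower) else as.numeric(d$lower), numeric(1))
  upper <- vapply(space, function(d)
    if (d$type == "log") log(d$upper) else as.numeric(d$upper), numeric(1))
  # a degenerate dimension (lower == upper) is kept but collapses in decode
  eps <- ifelse(upper == lower, 1e-9, 0)
  list(lower = lower, upper = upper + eps)
}

#' Decode an optimizer position into hyperparameters
#'
#' @param position Numeric vector in the internal bounds of `space`.
#' @param space A [tune_space()].
#' @return Named list of decoded values (integers for integer dims,
#'   exponentiated values for log dims).
#' @export
decode_position <- function(position, space) {
  stopifnot(inherits(space, "tune_space"))
  out <- purrr::imap(space, function(d, nm) {
    i <- match(nm, names(space))
    v <- position[i]
    v <- min(max(v, if (d$type == "log") log(d$lower) else d$lower),
             if (d$type == "log") log(d$upper) else d$upper)
    switch(d$type,
      continuous = v,
      log = exp(v),
      integer = as.integer(min(max(round(v), d$lower), d$upper))
    )
  })
  out
}

#' Tune hyperparameters with the chaotic sparrow search
#'
#' Wraps [cssa_optimize()] around a user objective that receives a decoded
#' named hyperparameter list and returns a fitness (typically the
#' validation [fitness_error_rate()]; lower is better).
#'
#' @param objective `function(hyper_list) -> fitness`.
#' @param space A [tune_space()].
#' @param N,T,seed Optimizer population, iterations and seed (forwarded to
#'   [cssa_config()]).
#' @param ... Further arguments to [cssa_config()].
#' @return A list of class `cssa_tune`: `best` (decoded hyperparameters),
#'   `best_fitness`, and the underlying `result`.
#' @export
cssa_tune <- function(objective, space = tune_space(), N = 10L, T = 10L,
                      seed = 1L, ...) {
  stopifnot(inherits(space, "tune_space"))
  if (length(space) == 0L) abort("`space` must declare at least one dimension.")
  b <- space_bounds(space)
  config <- cssa_config(N = N, D = length(space), T = T,
                        lower = b$lower, upper = b$upper, seed = seed, ...)
  wrapped <- function(x) objective(decode_position(x, space))
  result <- cssa_optimize(wrapped, config)
  structure(list(best = decode_position(result$best_position, space),
                 best_fitness = result$best_fitness, result = result,
                 space = space),
            class = "cssa_tune")
}

#' @export
print.cssa_tune <- function(x, ...) {
  cat("<cssa_tune> best fitness", format(x$best_fitness, digits = 6), "\n")
  for (nm in names(x$best)) {
    cat(sprintf("  %s = %s\n", nm, format(x$best[[nm]], digits = 6)))
  }
  invisible(x)
}

#' Best hyperparameters found by tuning
#' @param x A `cssa_tune`.
#' @param ... Unused.
#' @return One-row tibble of the decoded best values plus `best_fitness`.
#' @method tidy cssa_tune
#' @export
tidy.cssa_tune <- function(x, ...) {
  dplyr::bind_cols(tibble::as_tibble(x$best),
                   tibble::tibble(best_fitness = x$best_fitness))
}
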