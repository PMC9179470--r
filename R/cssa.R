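#' Chaotic sparrow search configuration
#'
#' Settings for the bound-constrained sparrow search minimizer with chaotic
#' local search. The population of `N` sparrows in `D` dimensions is split
#' each iteration into discoverers (best-fitness fraction `pd_frac`, which
#' lead the search), joiners (the rest, which follow or flee) and a random
#' vigilante subset (`sd_frac`) performing anti-predation moves. The
#' incumbent best is additionally perturbed by a logistic-map chaotic point
#' blended in with a linearly shrinking weight.
#'
#' @param N Population size (>= 4).
#' @param D Search dimension.
#' @param T Number of iterations (>= 1).
#' @param lower,upper Per-dimension bounds (scalars are recycled).
#' @param ST Safety threshold in `[0.5, 1]`; a uniform alarm value `R2`
#'   drawn each iteration switches the discoverer move when `R2 >= ST`.
#' @param pd_frac Discoverer fraction (default 0.2).
#' @param sd_frac Vigilante fraction (default 0.1).
#' @param e Small positive stabilizer in the vigilante denominator
#'   (default 1e-8).
#' @param mu Logistic-map control parameter; fixed at 4 (fully chaotic
#'   regime).
#' @param rho1 Chaotic seed in (0, 1), excluding the logistic map's
#'   rational fixed/periodic points 0.25, 0.5, 0.75.
#' @param seed Integer RNG seed.
#' @return An object of class `cssa_config`.
#' @export
cssa_config <- function(N = 20L, D, T = 100L, lower = -5, upper = 5,
                        ST = 0.8, pd_frac = 0.2, sd_frac = 0.1,
                        e = 1e-8, mu = 4, rho1 = 0.123, seed = 1L) {
  check_number(N, "N", positive = TRUE, integer = TRUE)
  check_number(D, "D", positive = TRUE, integer = TRUE)
  check_number(T, "T", positive = TRUE, integer = TRUE)
  if (N < 4L) abort("`N` must be at least 4.")
  if (ST < 0.5 || ST > 1) abort("`ST` must lie in [0.5, 1].")
  if (pd_frac <= 0 || pd_frac >= 1) abort("`pd_frac` must be in (0, 1).")
  if (sd_frac <= 0 || sd_frac >= 1) abort("`sd_frac` must be in (0, 1).")
  if (e <= 0) abort("`e` must be positive.")
  if (mu != 4) abort("`mu` is fixed at 4 (chaotic regime of the logistic map).")
  check_rho1(rho1)
  lower <- rep_len(as.numeric(lower), D)
  upper <- rep_len(as.numeric(upper), D)
  if (any(lower >= upper)) abort("Each lower bound must be below its upper bound.")
  structure(list(N = as.integer(N), D = as.integer(D), T = as.integer(T),
                 lower = lower, upper = upper, ST = ST, pd_frac = pd_frac,
                 sd_frac = sd_frac, e = e, mu = mu, rho1 = rho1,
                 seed = as.integer(seed)),
            class = "cssa_config")
}

check_rho1 <- function(rho1) {
  check_number(rho1, "rho1")
  if (rho1 <= 0 || rho1 >= 1 || rho1 %in% c(0.25, 0.5, 0.75)) {
    abort("`rho1` must lie in (0, 1) and avoid 0.25, 0.5, 0.75.")
  }
  invisible(rho1)
}

#' Logistic-map chaotic sequence
#'
#' Iterates `rho[k+1] = 4 * rho[k] * (1 - rho[k])` from `rho1`. At control
#' parameter 4 the map is fully chaotic on (0, 1) except at its rational
#' fixed and periodic points, which are rejected as seeds; every term stays
#' in `[0, 1]`.
#'
#' @param rho1 Seed in (0, 1), not one of 0.25, 0.5, 0.75.
#' @param length Number of terms to return (including `rho1`).
#' @return Numeric vector of `length` chaotic values.
#' @examples
#' logistic_map_sequence(0.3, 3) # 0.3, 0.84, 0.5376
#' @export
logistic_map_sequence <- function(rho1, length) {
  check_rho1(rho1)
  check_number(length, "length", positive = TRUE, integer = TRUE)
  out <- numeric(length)
  out[1] <- rho1
  if (length > 1) for (k in 2:length) out[k] <- 4 * out[k - 1] * (1 - out[k - 1])
  out
}

clip_bounds <- function(X, lower, upper) {
  X <- sweep(X, 2L, lower, pmax)
  sweep(X, 2L, upper, pmin)
}

#' Discoverer position update
#'
#' The best-fitness `pd_frac * N` sparrows lead the search. One alarm value
#' `R2 ~ U(0,1)` is drawn per iteration: when `R2 < ST` (no danger) each
#' discoverer contracts multiplicatively, `x <- x * exp(-i / (alpha * T))`
#' with rank `i` and `alpha ~ U(0, 1]` per sparrow; otherwise (predator
#' spotted) each moves by a shared normal step, `x <- x + Q` per
#' coordinate with `Q ~ N(0, 1)` scalar per sparrow. Results are clipped
#' to the bounds.
#'
#' @param X Position matrix of the discoverer subset (rows ranked best
#'   first, rank `i` = row number).
#' @param t Current iteration (unused by the formulas; kept for clarity).
#' @param config A [cssa_config()].
#' @param R2 The iteration's alarm value in `[0, 1]`.
#' @return Updated, clipped position matrix.
#' @export
update_discoverers <- function(X, t, config, R2 = runif(1)) {
  n <- nrow(X)
  if (n == 0L) return(X)
  if (R2 < config$ST) {
    alpha <- runif(n)
    alpha[alpha == 0] <- 1   # U(0, 1]: the exponent divides by alpha
    decay <- exp(-(seq_len(n)) / (alpha * config$T))
    X <- X * decay
  } else {
    Q <- rnorm(n)
    X <- X + Q   # Q * L with L the all-ones row: same offset per dimension
  }
  clip_bounds(X, config$lower, config$upper)
}

#' Joiner position update
#'
#' The non-discoverer sparrows with global fitness rank `i`: a hungry
#' joiner (`i > N/2`) flies elsewhere, `x_d <- Q * exp((x_worst_d - x_d) /
#' i^2)` with `Q ~ N(0,1)` per sparrow; a well-placed joiner (`i <= N/2`)
#' forages around the current best, adding to each coordinate of the best
#' position the mean over dimensions of `rand(-1,1) * |x_d - x_best_d|`
#' with a fresh uniform draw per dimension. Results are clipped.
#'
#' @param X Joiner position matrix.
#' @param ranks Global fitness ranks of these rows (1 = best).
#' @param x_best,x_worst Current best and worst positions.
#' @param config A [cssa_config()].
#' @return Updated, clipped position matrix.
#' @export
update_joiners <- function(X, ranks, x_best, x_worst, config) {
  n <- nrow(X)
  if (n == 0L) return(X)
  for (j in seq_len(n)) {
    i <- ranks[j]
    if (i > config$N / 2) {
      Q <- rnorm(1)
      X[j, ] <- Q * exp((x_worst - X[j, ]) / i^2)
    } else {
      off <- mean(runif(config$D, -1, 1) * abs(X[j, ] - x_best))
      X[j, ] <- x_best + off
    }
  }
  clip_bounds(X, config$lower, config$upper)
}

#' Vigilante position update
#'
#' A random `sd_frac * N` subset performs anti-predation moves. A sparrow
#' not at the global best (`f_i != f_g`, exposed at the population edge)
#' jumps relative to the worst position, `x_d <- x_worst_d + beta *
#' |x_d - x_worst_d|` with `beta ~ N(0,1)` scalar per sparrow. The sparrow
#' at the global best (`f_i = f_g`, center of the flock) steps by
#' `K * |x_d - x_worst_d| / ((f_i - f_w) + e)` with `K ~ U(-1,1)`; the
#' stabilizer `e > 0` guards the denominator when best and worst fitness
#' coincide. Results are clipped.
#'
#' @param X Vigilante position matrix.
#' @param fit Fitness of these rows.
#' @param f_g,f_w Current global best and worst fitness.
#' @param x_worst Current worst position.
#' @param config A [cssa_config()].
#' @return Updated, clipped position matrix.
#' @export
update_vigilantes <- function(X, fit, f_g, f_w, x_worst, config) {
  n <- nrow(X)
  if (n == 0L) return(X)
  for (j in seq_len(n)) {
    if (fit[j] != f_g) {
      beta <- rnorm(1)
      X[j, ] <- x_worst + beta * abs(X[j, ] - x_worst)
    } else {
      denom <- (fit[j] - f_w) + config$e
      if (abs(denom) < config$e / 2) {
        warn("Vigilante denominator close to zero; step may be large.")
      }
      K <- runif(1, -1, 1)
      X[j, ] <- X[j, ] + K * abs(X[j, ] - x_worst) / denom
    }
  }
  clip_bounds(X, config$lower, config$upper)
}

#' Chaotic local-search candidate
#'
#' Maps the chaotic value `rho` into the box as `P_d = a_d + rho *
#' (b_d - a_d)`, then blends it with the target (incumbent best) position
#' using the linear shrink coefficient `SC = (T - t + 1) / T`:
#' `CL = (1 - SC) * TP + SC * P`. Early iterations (`SC` near 1) explore
#' the chaotic point; late ones stay near the incumbent. Since `CL` is a
#' convex combination of two in-box points it is feasible by construction.
#'
#' @param x_best Target position `TP`.
#' @param rho Chaotic value in `[0, 1]` (see [logistic_map_sequence()]).
#' @param t Current iteration in `[1, T]`.
#' @param config A [cssa_config()].
#' @return Candidate position vector.
#' @export
chaotic_candidate <- function(x_best, rho, t, config) {
  if (t < 1 || t > config$T) abort("`t` must lie in [1, T].")
  P <- config$lower + rho * (config$upper - config$lower)
  SC <- (config$T - t + 1) / config$T
  (1 - SC) * x_best + SC * P
}

#' Classification error-rate fitness
#'
#' The percentage of misclassified samples, `100 * #wrong / n`; the
#' quantity the optimizer minimizes, equal to `100 -` overall accuracy
#' percent.
#'
#' @param predictions,truth Equal-length nonempty label vectors.
#' @return Error rate in percent.
#' @examples
#' fitness_error_rate(c(1, 2, 2), c(1, 2, 1)) # 33.33...
#' @export
fitness_error_rate <- function(predictions, truth) {
  if (length(predictions) == 0L || length(predictions) != length(truth)) {
    abort("`predictions` and `truth` must be nonempty and of equal length.")
  }
  100 * mean(as.character(predictions) != as.character(truth))
}

#' Run the chaotic sparrow search minimizer
#'
#' Initializes `N` positions uniformly in the box, then for `T` iterations
#' applies the discoverer, joiner and vigilante updates, re-evaluates all
#' fitness values, and finally proposes a [chaotic_candidate()] built from
#' the incumbent best, accepting it only on strict improvement (greedy
#' elitism). The recorded best fitness is therefore non-increasing.
#'
#' @param objective Function mapping a position vector to a scalar fitness
#'   (lower is better); must be deterministic given the position.
#' @param config A [cssa_config()].
#' @return An object of class `cssa_result`: `best_position`,
#'   `best_fitness`, a per-iteration `history` tibble (`iteration`, `f_g`,
#'   `mean_fitness`) and the number of objective `evaluations`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- cssa_optimize(sphere, cssa_config(N = 10, D = 2, T = 20, seed = 1))
#' res$best_fitness
#' @export
cssa_optimize <- function(objective, config) {
  stopifnot(inherits(config, "cssa_config"))
  eval_fit <- function(X) apply(X, 1L, function(x) {
    f <- objective(x)
    if (!is.finite(f)) abort("Objective returned a non-finite fitness.")
    f
  })
  with_seed(config$seed, {
    N <- config$N; D <- config$D
    X <- sapply(seq_len(D), function(d)
      runif(N, config$lower[d], config$upper[d]))
    X <- matrix(X, N, D)
    fit <- eval_fit(X)
    evals <- N
    rho <- config$rho1
    best_i <- which.min(fit)
    x_best <- X[best_i, ]; f_g <- fit[best_i]
    history <- vector("list", config$T)
    n_pd <- max(1L, round(config$pd_frac * N))
    n_sd <- max(1L, round(config$sd_frac * N))
    for (t in seq_len(config$T)) {
      ord <- order(fit)
      worst_i <- ord[N]
      x_worst <- X[worst_i, ]
      f_w <- fit[worst_i]
      disc <- ord[seq_len(n_pd)]
      join <- ord[-seq_len(n_pd)]
      R2 <- runif(1)
      X[disc, ] <- update_discoverers(X[disc, , drop = FALSE], t, config,
                                      R2 = R2)
      # joiners follow the best discoverer position after its move
      xb_new <- X[disc[1L], ]
      X[join, ] <- update_joiners(X[join, , drop = FALSE],
                                  ranks = seq_len(N)[-seq_len(n_pd)],
                                  x_best = xb_new, x_worst = x_worst,
                                  config = config)
      vig <- sample.int(N, n_sd)
      X[vig, ] <- update_vigilantes(X[vig, , drop = FALSE], fit[vig],
                                    f_g = f_g, f_w = f_w,
                                    x_worst = x_worst, config = config)
      fit <- eval_fit(X)
      evals <- evals + N
      i <- which.min(fit)
      if (fit[i] < f_g) { f_g <- fit[i]; x_best <- X[i, ] }
      rho <- 4 * rho * (1 - rho)
      cl <- chaotic_candidate(x_best, rho, t, config)
      f_cl <- objective(cl)
      evals <- evals + 1L
      if (is.finite(f_cl) && f_cl < f_g) {
        f_g <- f_cl; x_best <- cl
        # the candidate replaces the current worst population member
        wi <- which.max(fit)
        X[wi, ] <- cl; fit[wi] <- f_cl
      }
      history[[t]] <- tibble::tibble(iteration = t, f_g = f_g,
                                     mean_fitness = mean(fit))
    }
    structure(list(best_position = x_best, best_fitness = f_g,
                   history = dplyr::bind_rows(history),
                   evaluations = evals, config = config),
              class = "cssa_result")
  })
}

#' @export
print.cssa_result <- function(x, ...) {
  cat(sprintf(
    "<cssa_result> D=%d, N=%d, T=%d: best fitness %.6g (%d evaluations)\n",
    x$config$D, x$config$N, x$config$T, x$best_fitness, x$evaluations))
  invisible(x)
}

#' Iteration history of a sparrow search run
#' @param x A `cssa_result`.
#' @param ... Unused.
#' @return Tibble with `iteration`, `f_g` (incumbent best) and
#'   `mean_fitness`.
#' @method tidy cssa_result
#' @export
tidy.cssa_result <- function(x, ...) x$history

#' One-row summary of a sparrow search run
#' @param x A `cssa_result`.
#' @param ... Unused.
#' @method glance cssa_result
#' @export
glance.cssa_result <- function(x, ...) {
  tibble::tibble(D = x$config$D, N = x$config$N, T = x$config$T,
                 best_fitness = x$best_fitness, evaluations = x$evaluations)
}
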