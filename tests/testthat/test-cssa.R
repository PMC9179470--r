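test_that("logistic map reproduces known terms, rejects fixed points, stays bounded", {
  expect_equal(logistic_map_sequence(0.3, 3), c(0.3, 0.84, 0.5376),
               tolerance = 1e-12)
  expect_error(logistic_map_sequence(0.75, 5), "avoid")
  expect_error(logistic_map_sequence(0.25, 5), "avoid")
  expect_error(logistic_map_sequence(0.5, 5), "avoid")
  expect_error(logistic_map_sequence(1, 5), "avoid")
  long <- logistic_map_sequence(0.123, 10000)
  expect_true(all(long >= 0 & long <= 1))
})

test_that("the chaotic candidate blends best and chaotic points convexly", {
  cfg <- cssa_config(N = 4, D = 1, T = 2, lower = 0, upper = 1, seed = 1)
  # t = 1: shrink coefficient 1, candidate is the chaotic point entirely
  expect_equal(chaotic_candidate(0.9, 0.3, 1, cfg), 0.3)
  # t = T = 2: SC = 1/2, CL = 0.5 * 0.9 + 0.5 * 0.3
  expect_equal(chaotic_candidate(0.9, 0.3, 2, cfg), 0.6)
  bigT <- cssa_config(N = 4, D = 1, T = 1000, lower = 0, upper = 1, seed = 1)
  expect_equal(chaotic_candidate(0.9, 0.3, 1000, bigT), 0.9,
               tolerance = 1e-2)
  # always a convex combination, hence inside the box
  cfg3 <- cssa_config(N = 4, D = 3, T = 10, lower = c(-1, 0, 2),
                      upper = c(1, 5, 3), seed = 1)
  set.seed(2)
  for (i in 1:25) {
    xb <- runif(3, cfg3$lower, cfg3$upper)
    cl <- chaotic_candidate(xb, runif(1), sample(10, 1), cfg3)
    expect_true(all(cl >= cfg3$lower & cl <= cfg3$upper))
  }
  expect_error(chaotic_candidate(0.5, 0.3, 0, cfg), "lie in")
})

test_that("error-rate fitness is the complement of overall accuracy", {
  expect_equal(fitness_error_rate(c(rep(1, 90), rep(2, 10)), rep(1, 100)), 10)
  expect_equal(fitness_error_rate(1:5, 1:5), 0)
  expect_equal(fitness_error_rate(rep(2, 4), rep(1, 4)), 100)
  expect_error(fitness_error_rate(integer(0), integer(0)), "nonempty")
  set.seed(3)
  y <- sample(letters[1:4], 60, replace = TRUE)
  p <- sample(letters[1:4], 60, replace = TRUE)
  cm <- build_confusion(y, p, labels = letters[1:4])
  expect_equal(fitness_error_rate(p, y), 100 - overall_accuracy(cm),
               tolerance = 1e-12)
})

test_that("discoverer updates follow both alarm branches and clip to bounds", {
  cfg <- cssa_config(N = 10, D = 3, T = 10, lower = -2, upper = 2,
                     ST = 0.8, seed = 1)
  X <- matrix(1, 4, 3)
  # calm branch: replicate the alpha draws, expect x * exp(-i / (alpha T))
  set.seed(55); alpha <- runif(4)
  set.seed(55)
  upd <- update_discoverers(X, t = 1, cfg, R2 = 0.1)
  expect_equal(upd, X * exp(-(1:4) / (alpha * 10)), tolerance = 1e-12)
  # alarm branch: a shared normal step per sparrow on every coordinate
  set.seed(56); Q <- rnorm(4)
  set.seed(56)
  upd2 <- update_discoverers(X, t = 1, cfg, R2 = 0.95)
  expect_equal(upd2, pmin(pmax(X + Q, -2), 2), tolerance = 1e-12)
  # clipping lands exactly on the bound
  Xlow <- matrix(-1.999, 2, 3)
  set.seed(60); Q2 <- rnorm(2)
  set.seed(60)
  upd3 <- update_discoverers(Xlow, t = 1, cfg, R2 = 0.95)
  expect_true(all(upd3 >= -2 & upd3 <= 2))
  expect_equal(upd3, pmin(pmax(Xlow + Q2, -2), 2))
})

test_that("joiner updates handle the hungry and foraging branches", {
  cfg <- cssa_config(N = 8, D = 3, T = 10, lower = -5, upper = 5, seed = 1)
  x_best <- c(1, 2, 3); x_worst <- c(-4, -4, -4)
  # a joiner sitting at the best position stays there (|0| term vanishes)
  X <- matrix(x_best, 1, 3, byrow = TRUE)
  set.seed(1)
  expect_equal(update_joiners(X, ranks = 3, x_best, x_worst, cfg),
               matrix(x_best, 1, 3, byrow = TRUE), tolerance = 1e-12)
  # hungry branch at the worst position: exponent zero, position Q per dim
  Xw <- matrix(x_worst, 1, 3, byrow = TRUE)
  set.seed(9); Q <- rnorm(1)
  set.seed(9)
  upd <- update_joiners(Xw, ranks = 7, x_best, x_worst, cfg)
  expect_equal(upd, matrix(pmin(pmax(Q, -5), 5), 1, 3), tolerance = 1e-12)
})

test_that("vigilante updates cover the edge, center and guard paths", {
  cfg <- cssa_config(N = 8, D = 2, T = 10, lower = -50, upper = 50,
                     e = 1e-8, seed = 1)
  x_worst <- c(2, -3)
  # at the best fitness and at the worst position: step numerator is zero
  Xw <- matrix(x_worst, 1, 2, byrow = TRUE)
  set.seed(2)
  expect_equal(update_vigilantes(Xw, fit = 1, f_g = 1, f_w = 5, x_worst, cfg),
               Xw)
  # edge sparrow: x_worst + beta * |x - x_worst| with the replicated beta
  X <- matrix(c(4, 1), 1, 2, byrow = TRUE)
  set.seed(13); beta <- rnorm(1)
  set.seed(13)
  upd <- update_vigilantes(X, fit = 3, f_g = 1, f_w = 5, x_worst, cfg)
  expect_equal(upd, matrix(pmin(pmax(x_worst + beta * abs(c(4, 1) - x_worst),
                                     -50), 50), 1, 2), tolerance = 1e-12)
  # guard path: best == worst fitness, step = K * v / e exactly
  cfg2 <- cssa_config(N = 8, D = 1, T = 10, lower = -1e10, upper = 1e10,
                      e = 0.5, seed = 1)
  X1 <- matrix(3, 1, 1)
  set.seed(21); K <- runif(1, -1, 1)
  set.seed(21)
  upd2 <- suppressWarnings(
    update_vigilantes(X1, fit = 2, f_g = 2, f_w = 2, x_worst = 1, cfg2))
  expect_equal(upd2[1, 1], 3 + K * abs(3 - 1) / 0.5, tolerance = 1e-12)
})

test_that("configuration constraints are enforced", {
  expect_error(cssa_config(N = 3, D = 2, T = 5), "at least 4")
  expect_error(cssa_config(N = 5, D = 2, T = 5, ST = 0.4), "0.5")
  expect_error(cssa_config(N = 5, D = 2, T = 5, mu = 3.9), "fixed at 4")
  expect_error(cssa_config(N = 5, D = 2, T = 5, rho1 = 0.5), "avoid")
  expect_error(cssa_config(N = 5, D = 2, T = 5, lower = 1, upper = 1),
               "below")
})

test_that("the optimizer minimizes the sphere and keeps invariants", {
  cfg <- cssa_config(N = 20, D = 5, T = 100, lower = -5, upper = 5, seed = 4)
  res <- cssa_optimize(fn_sphere, cfg)
  expect_lt(res$best_fitness, 1e-2)
  expect_true(all(diff(res$history$f_g) <= 0))
  expect_equal(nrow(res$history), 100L)
  # strictly better than the best of 2000 uniform random samples
  set.seed(4)
  rand_best <- min(apply(matrix(runif(2000 * 5, -5, 5), 2000, 5), 1,
                         fn_sphere))
  expect_lt(res$best_fitness, rand_best)
  # determinism and the T = 1 degenerate case
  res2 <- cssa_optimize(fn_sphere, cfg)
  expect_identical(res$history, res2$history)
  cfg1 <- cssa_config(N = 8, D = 3, T = 1, lower = -5, upper = 5, seed = 2)
  r1 <- cssa_optimize(fn_sphere, cfg1)
  set.seed(2)
  init_best <- min(apply(matrix(
    sapply(1:3, function(d) runif(8, -5, 5)), 8, 3), 1, fn_sphere))
  expect_equal(nrow(r1$history), 1L)
  expect_lte(r1$best_fitness, init_best)
})

test_that("every phase keeps all positions inside the box and f_g monotone", {
  # the objective records every position it is asked to evaluate
  for (seed in c(1, 7, 13)) {
    for (fn in list(fn_sphere, fn_rosenbrock, fn_rastrigin)) {
      seen_out <- FALSE
      wrapped <- function(x) {
        if (any(x < -2.5 - 1e-12) || any(x > 2.5 + 1e-12)) seen_out <<- TRUE
        fn(x)
      }
      res <- cssa_optimize(wrapped, cssa_config(N = 10, D = 3, T = 25,
                                                lower = -2.5, upper = 2.5,
                                                seed = seed))
      expect_false(seen_out)
      expect_true(all(diff(res$history$f_g) <= 0))
      expect_true(all(res$best_position >= -2.5 & res$best_position <= 2.5))
    }
  }
})

test_that("hyperparameter tuning decodes positions and recovers a 1-D optimum", {
  # log-scale 1-D recovery: quadratic in log-space around lr = 0.01
  space <- tune_space(learning_rate = list(lower = 1e-3, upper = 1e-1,
                                           type = "log"))
  ts <- cssa_tune(function(h) (log(h$learning_rate) - log(0.01))^2,
                  space = space, N = 10, T = 30, seed = 5)
  expect_lt(abs(ts$best$learning_rate - 0.01), 0.1 * 0.01)
  # integer dimensions always decode to in-range integers
  space2 <- tune_space(hidden = list(lower = 4, upper = 64,
                                     type = "integer"))
  ts2 <- cssa_tune(function(h) {
    expect_true(h$hidden == as.integer(h$hidden) &&
                h$hidden >= 4 && h$hidden <= 64)
    abs(h$hidden - 13)
  }, space = space2, N = 6, T = 8, seed = 2)
  expect_equal(ts2$best$hidden, 13L)
  # a degenerate dimension returns its constant
  space3 <- tune_space(fixed = list(lower = 2, upper = 2,
                                    type = "continuous"))
  ts3 <- cssa_tune(function(h) h$fixed^2, space = space3, N = 4, T = 2,
                   seed = 1)
  expect_equal(ts3$best$fixed, 2, tolerance = 1e-6)
  expect_s3_class(tidy(ts3), "tbl_df")
})
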