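test_that("the GRU cell reduces correctly at zero weights and saturation", {
  p <- gru_layer_params(3, 4, seed = 1)
  for (nm in names(p)) p[[nm]] <- p[[nm]] * 0
  h_prev <- c(0.4, -0.2, 0.8, 0.1)
  st <- gru_cell_step(c(1, 2, 3), h_prev, p)
  expect_equal(st$u, rep(0.5, 4))
  expect_equal(st$r, rep(0.5, 4))
  expect_equal(st$candidate, rep(0, 4))
  expect_equal(st$h, 0.5 * h_prev)
  # large update-gate bias saturates u toward 1, h toward the candidate
  p$bu <- rep(50, 4)
  st2 <- gru_cell_step(c(1, 2, 3), h_prev, p)
  expect_equal(st2$h, st2$candidate, tolerance = 1e-12)
  expect_error(gru_cell_step(c(1, 2), h_prev, p), "input size")
  expect_error(gru_cell_step(c(1, 2, 3), h_prev[1:2], p), "hidden size")
})

test_that("the cell matches a scalar-loop oracle on random instances", {
  set.seed(31)
  for (i in 1:5) {
    p <- gru_layer_params(2, 2, seed = i)
    x <- rnorm(2); h <- rnorm(2)
    fast <- gru_cell_step(x, h, p)
    slow <- oracle_gru_cell(x, h, p)
    for (nm in c("u", "r", "candidate", "h")) {
      expect_equal(fast[[nm]], slow[[nm]], tolerance = 1e-12)
    }
  }
})

test_that("gate ranges stay in their open intervals over random steps", {
  set.seed(99)
  p <- gru_layer_params(3, 5, seed = 12, scale = 2)
  for (i in 1:1000) {
    st <- gru_cell_step(rnorm(3, sd = 2), rnorm(5), p)
    expect_true(all(st$u > 0 & st$u < 1))
    expect_true(all(st$r > 0 & st$r < 1))
    expect_true(all(st$candidate > -1 & st$candidate < 1))
  }
})

test_that("zero-weight recursion contracts the hidden state geometrically", {
  p <- gru_layer_params(2, 3, seed = 5)
  for (nm in names(p)) p[[nm]] <- p[[nm]] * 0
  h <- c(1, -2, 0.5)
  norms <- numeric(6)
  for (tt in 1:6) {
    h <- gru_cell_step(c(0, 0), h, p)$h
    norms[tt] <- sqrt(sum(h^2))
  }
  expect_true(all(diff(norms) < 0))
  expect_equal(norms[6] / norms[5], 0.5, tolerance = 1e-12)
})

test_that("feature chunking partitions the vector deterministically", {
  v <- seq_len(64)
  s <- featuremap_to_sequence(v, 16)
  expect_equal(dim(s), c(4L, 16L))
  expect_equal(as.numeric(t(s)), as.numeric(v))   # round-trip concatenation
  expect_equal(nrow(featuremap_to_sequence(v, 64)), 1L)
  expect_error(featuremap_to_sequence(v, 65), "exceeds")
  expect_error(featuremap_to_sequence(v, 7), "divisible")
})

test_that("stacked forward agrees with the unrolled oracle and sums to one", {
  set.seed(17)
  stack <- list(gru_layer_params(4, 3, seed = 2),
                gru_layer_params(3, 3, seed = 3))
  head <- list(W = matrix(rnorm(2 * 3), 2, 3), b = rnorm(2))
  seqm <- matrix(rnorm(12), 3, 4)
  probs <- sgru_forward(seqm, stack, head)
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  expect_lt(max(abs(probs - oracle_sgru_forward(seqm, stack, head))), 1e-10)
  # single layer, single step reduces to cell + head
  st <- gru_cell_step(seqm[1, ], rep(0, 3), stack[[1]])
  logits <- drop(head$W %*% st$h) + head$b
  expect_equal(sgru_forward(seqm[1, , drop = FALSE], stack[1], head),
               exp(logits - max(logits)) / sum(exp(logits - max(logits))),
               tolerance = 1e-12)
  # zero head weights give the uniform distribution
  expect_equal(sgru_forward(seqm, stack, list(W = matrix(0, 5, 3),
                                              b = rep(0, 5))),
               rep(0.2, 5))
  expect_error(sgru_forward(matrix(numeric(0), 0, 4), stack, head),
               "nonempty")
})

test_that("analytic gradients match central finite differences", {
  set.seed(23)
  x <- matrix(rnorm(8), 2, 4)
  stack <- list(gru_layer_params(4, 3, seed = 11),
                gru_layer_params(3, 3, seed = 12))
  head <- list(W = matrix(rnorm(6, sd = 0.4), 2, 3), b = rnorm(2))
  loss <- function(st, hd) -log(sgru_forward(x, st, hd)[1])
  fwd <- sgru_forward(x, stack, head, details = TRUE)
  bk <- sparrowtex:::sgru_backward(fwd, stack, head, 1)
  eps <- 1e-6
  worst <- 0
  for (l in 1:2) {
    for (nm in names(stack[[l]])) {
      for (i in seq_along(stack[[l]][[nm]])) {
        sp <- stack; sp[[l]][[nm]][i] <- sp[[l]][[nm]][i] + eps
        sm <- stack; sm[[l]][[nm]][i] <- sm[[l]][[nm]][i] - eps
        num <- (loss(sp, head) - loss(sm, head)) / (2 * eps)
        worst <- max(worst, abs(num - bk$layers[[l]][[nm]][i]))
      }
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("training separates a separable toy set and is seed-deterministic", {
  set.seed(1)
  x <- rbind(matrix(rnorm(40 * 8, mean = 1), 40, 8),
             matrix(rnorm(40 * 8, mean = -1), 40, 8))
  y <- rep(c("a", "b"), each = 40)
  fit <- train_classifier(x, y, hyper = list(epochs = 50, hidden_size = 8,
                                             steps = 2), seed = 7)
  expect_equal(tail(fit$history$train_accuracy, 1), 1)
  expect_equal(nrow(fit$history), 50L)
  fit2 <- train_classifier(x, y, hyper = list(epochs = 5, hidden_size = 8,
                                              steps = 2), seed = 7)
  fit3 <- train_classifier(x, y, hyper = list(epochs = 5, hidden_size = 8,
                                              steps = 2), seed = 7)
  expect_identical(fit2$stack, fit3$stack)
  expect_identical(fit2$head, fit3$head)
  # zero epochs returns the initialization untouched
  fit0 <- train_classifier(x, y, hyper = list(epochs = 0, hidden_size = 8,
                                              steps = 2), seed = 7)
  init <- sparrowtex:::init_sgru(4, 8, 2, 2, 7)
  expect_identical(fit0$stack, init$stack)
  expect_identical(fit0$head, init$head)
  expect_equal(nrow(fit0$history), 0L)
})

test_that("prediction returns tidy probabilities consistent with forward", {
  set.seed(2)
  x <- matrix(rnorm(10 * 8), 10, 8)
  y <- rep(c("u", "v"), 5)
  fit <- train_classifier(x, y, hyper = list(epochs = 2, hidden_size = 4,
                                             steps = 2), seed = 3)
  pred <- predict(fit, x)
  expect_named(pred, c(".pred_class", ".prob_u", ".prob_v"))
  expect_equal(rowSums(as.matrix(pred[, 2:3])), rep(1, 10),
               tolerance = 1e-12)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1L)
})
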