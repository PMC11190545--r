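test_that("the weight count follows the architecture", {
  # 4 matrices hidden x (hidden+input), 4 hidden biases, output layer
  expect_equal(gru_spec(16, 8)$n_weights, 4 * (8 * 24 + 8) + 8 + 1)
  expect_equal(gru_spec(32, 8)$n_weights, 4 * (8 * 40 + 8) + 8 + 1)
  expect_equal(gru_spec(1, 1)$n_weights, 4 * (1 * 2 + 1) + 2)
})

test_that("the flat-vector codec round-trips exactly", {
  spec <- gru_spec(5, 3)
  v <- withr::with_seed(1, runif(spec$n_weights, -2, 2))
  w <- gru_decode(spec, v)
  expect_identical(gru_encode(w), v)
  z <- gru_decode(spec, rep(0, spec$n_weights))
  expect_true(all(gru_encode(z) == 0))
  expect_true(all(z$Wi == 0) && all(z$b == 0))
  expect_error(gru_decode(spec, rep(0, spec$n_weights - 1)), "length")
})

test_that("the cell behaves as derived for zero weights", {
  spec <- gru_spec(4, 3)
  w <- gru_decode(spec, rep(0, spec$n_weights))
  x <- rep(0.7, 4)
  # z = 0.5, htilde = 0: h = 0.5 * h_prev
  expect_equal(gru_cell_step(w, rep(0, 3), x), rep(0, 3))
  expect_equal(gru_cell_step(w, rep(1, 3), x), rep(0.5, 3))
  expect_error(gru_cell_step(w, rep(0, 2), x), "sizes")
})

test_that("the hidden state stays in [-1, 1] for any weights and inputs", {
  spec <- gru_spec(6, 4)
  for (seed in 1:5) {
    w <- random_gru_weights(spec, seed)
    h <- withr::with_seed(seed + 50, runif(4, -1, 1))
    x <- withr::with_seed(seed + 60, runif(6, -3, 3)) # even wild inputs
    for (t in 1:10) {
      h <- gru_cell_step(w, h, x)
      expect_true(all(h >= -1 & h <= 1))
    }
  }
})

test_that("zero weights produce probability one half for any sequence", {
  spec <- gru_spec(4, 3)
  w <- gru_decode(spec, rep(0, spec$n_weights))
  s <- withr::with_seed(2, matrix(runif(5 * 4), 5, 4))
  expect_equal(gru_forward(w, s), 0.5)
})

test_that("the vectorized forward pass matches the scalar-loop oracle", {
  spec <- gru_spec(5, 4)
  for (seed in 1:5) {
    w <- random_gru_weights(spec, seed)
    s <- withr::with_seed(seed + 10, matrix(runif(6 * 5), 6, 5))
    expect_equal(gru_forward(w, s), oracle_gru_forward(w, s),
                 tolerance = 1e-10)
    expect_gt(gru_forward(w, s), 0)
    expect_lt(gru_forward(w, s), 1)
  }
  # batched equals per-sequence
  x <- withr::with_seed(99, array(runif(3 * 6 * 5), c(3, 6, 5)))
  w <- random_gru_weights(spec, 1)
  batched <- gru_forward(w, x)
  single <- sapply(1:3, function(i) gru_forward(w, x[i, , ]))
  expect_equal(batched, single, tolerance = 1e-12)
})

test_that("empty sequences are rejected", {
  spec <- gru_spec(4, 3)
  w <- gru_decode(spec, rep(0, spec$n_weights))
  expect_error(gru_forward(w, array(0, c(2, 0, 4))), "timestep")
})

test_that("the MSE fitness follows its definition", {
  spec <- gru_spec(3, 2)
  x <- withr::with_seed(1, array(runif(2 * 4 * 3), c(2, 4, 3)))
  # force outputs ~0 via a strongly negative output bias
  v <- rep(0, spec$n_weights)
  v[spec$n_weights] <- -40
  expect_equal(gru_fitness(v, spec, x, y = c(1, 0)), 0.5, tolerance = 1e-8)
  # zero weights -> p = 0.5 everywhere
  expect_equal(gru_fitness(rep(0, spec$n_weights), spec, x, y = c(1, 0)),
               0.25)
  # a label vector matching the outputs gives ~0
  v[spec$n_weights] <- 40
  expect_equal(gru_fitness(v, spec, x, y = c(1, 1)), 0, tolerance = 1e-8)
  expect_error(gru_fitness(v, spec, array(0, c(0, 4, 3)), numeric(0)),
               "nonempty")
})

test_that("training learns a separable toy problem and is elitist", {
  # class 1 sequences have high mean, class 0 low mean
  n <- 20; Tn <- 4; D <- 4
  x <- withr::with_seed(8, {
    a <- array(runif(n * Tn * D), c(n, Tn, D))
    a[1:(n / 2), , ] <- a[1:(n / 2), , ] * 0.3 + 0.7
    a[(n / 2 + 1):n, , ] <- a[(n / 2 + 1):n, , ] * 0.3
    a
  })
  y <- rep(c(1, 0), each = n / 2)
  fit <- gru_train(x, y, spec = gru_spec(D, 3),
                   config = ngo_config(n = 10, iterations = 60, seed = 4))
  expect_lt(fit$train_fitness, 0.25) # beats the all-0.5 baseline
  expect_gte(fit$train_accuracy, 0.9)
  expect_lte(fit$train_fitness, fit$result$history[1]) # elitism
  expect_length(fit$result$history, 60)
  # determinism
  fit2 <- gru_train(x, y, spec = gru_spec(D, 3),
                    config = ngo_config(n = 10, iterations = 60, seed = 4))
  expect_identical(fit$weight_vector, fit2$weight_vector)
  # one-iteration run
  fit1 <- gru_train(x, y, spec = gru_spec(D, 3),
                    config = ngo_config(n = 5, iterations = 1, seed = 1))
  expect_length(fit1$result$history, 1)
})

test_that("model serialization round-trips predictions", {
  spec <- gru_spec(4, 3)
  x <- withr::with_seed(3, array(runif(4 * 5 * 4), c(4, 5, 4)))
  fit <- gru_train(x, c(1, 1, 0, 0), spec = spec,
                   config = ngo_config(n = 5, iterations = 5, seed = 2))
  f <- withr::local_tempfile(fileext = ".json")
  save_gru_fit(fit, f)
  fit2 <- load_gru_fit(f)
  expect_equal(predict(fit2, x), predict(fit, x), tolerance = 1e-12)
  expect_equal(predict(fit, x, type = "class"),
               as.integer(predict(fit, x) >= 0.5))
  lab <- predict(fit, x, type = "label")
  expect_true(all(lab %in% c("cancerous", "non-cancerous")))
})

test_that("tidy and glance summarize a fit", {
  x <- withr::with_seed(5, array(runif(4 * 3 * 4), c(4, 3, 4)))
  fit <- gru_train(x, c(1, 0, 1, 0), spec = gru_spec(4, 2),
                   config = ngo_config(n = 5, iterations = 8, seed = 3))
  expect_equal(nrow(tidy(fit)), 8)
  gl <- glance(fit)
  expect_equal(gl$train_fitness, fit$train_fitness)
  expect_equal(gl$n_weights, gru_spec(4, 2)$n_weights)
})
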