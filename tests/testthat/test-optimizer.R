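test_that("population initialization is bounded, seeded and size-checked", {
  p <- bench_problem("Sphere", 30)
  pop <- ngo_init_population(p, n = 5, seed = 7)
  expect_equal(dim(pop$Z), c(5, 30))
  expect_true(all(pop$Z >= -100 & pop$Z <= 100))
  expect_equal(pop$P, p$fn_matrix(pop$Z))
  expect_identical(pop, ngo_init_population(p, n = 5, seed = 7))
  expect_false(identical(pop$Z, ngo_init_population(p, n = 5, seed = 8)$Z))
  expect_error(ngo_init_population(p, n = 1, seed = 1), "at least 2")
})

test_that("candidate formulas reproduce hand substitutions", {
  # exploration: z = 1, prey = 2
  expect_equal(ngo_explore_candidate(1, 2, step = 0.5, I = 1,
                                     prey_better = TRUE), 1.5)
  expect_equal(ngo_explore_candidate(1, 2, step = 0.5, I = 1,
                                     prey_better = FALSE), 0.5)
  expect_equal(ngo_explore_candidate(1, 2, step = 0.5, I = 2,
                                     prey_better = TRUE), 1)
  # exploitation: z = 10, R = 0.02, r = 1
  expect_equal(ngo_exploit_candidate(10, 0.02, 1), 10.2)
  expect_equal(ngo_exploit_candidate(10, 0.02, 0), 9.8)
  # radius schedule
  expect_equal(ngo_radius(0, 900), 0.02)
  expect_equal(ngo_radius(900, 900), 0)
  expect_equal(ngo_radius(450, 900), 0.01)
})

test_that("greedy acceptance keeps the incumbent when the candidate is worse", {
  # individual at the optimum cannot be improved: forced step away
  Z <- rbind(c(0, 0), c(3, 3))
  p <- bench_problem("Sphere", 2)
  P <- p$fn_matrix(Z)
  draws <- list(k = c(2L, 1L), I = c(1L, 1L),
                step = matrix(0.5, 2, 2), r2 = matrix(1, 2, 2))
  out <- ngo_iteration(Z, P, p$fn_matrix, p$lower, p$upper, t = 0,
                       iterations = 10, variant = "ngo", draws = draws)
  expect_equal(out$Z[1, ], c(0, 0)) # unchanged at the optimum
  expect_equal(out$P[1], 0)
  expect_lte(out$P[2], P[2]) # never worse
})

test_that("runs are elitist, bounded, reproducible and seed-sensitive", {
  p <- bench_problem("Sphere", 5)
  cfg <- ngo_config(n = 10, iterations = 40, seed = 3)
  res <- ngo_optimize(p, cfg)
  expect_true(all(diff(res$history) <= 0))
  expect_equal(res$best_value, min(res$history))
  expect_equal(res$best_value, res$history[length(res$history)])
  expect_true(all(res$best_position >= p$lower & res$best_position <= p$upper))
  expect_equal(res$n_evaluations, 10 + 2 * 10 * 40)
  res2 <- ngo_optimize(p, cfg)
  expect_identical(res$history, res2$history)
  expect_identical(res$best_position, res2$best_position)
  res3 <- ngo_optimize(p, ngo_config(n = 10, iterations = 40, seed = 4))
  expect_false(identical(res$history, res3$history))
})

test_that("both variants converge on Sphere d=2 and beat random search 10x", {
  p <- bench_problem("Sphere", 2)
  budget <- 20 + 2 * 20 * 200
  rs_best <- withr::with_seed(31, {
    Z <- matrix(runif(budget * 2, -100, 100), budget, 2)
    min(p$fn_matrix(Z))
  })
  for (variant in c("ngo", "ngo-lc")) {
    res <- ngo_optimize(p, ngo_config(n = 20, iterations = 200, seed = 5,
                                      variant = variant))
    expect_lt(res$best_value, 1e-3, label = variant)
    expect_lt(res$best_value, rs_best / 10, label = variant)
  }
})

test_that("a single-iteration run has the expected structure", {
  p <- bench_problem("Sphere", 3)
  res <- ngo_optimize(p, ngo_config(n = 2, iterations = 1, seed = 1))
  expect_length(res$history, 1)
  expect_equal(res$n_evaluations, 2 + 2 * 2)
})

test_that("non-finite candidate evaluations are rejected with a warning", {
  bad <- function(Z) ifelse(abs(Z[, 1]) < 50, NaN, rowSums(Z^2))
  expect_warning(
    res <- ngo_optimize(bad, ngo_config(n = 5, iterations = 5, seed = 2),
                        lower = rep(-100, 2), upper = rep(100, 2)),
    "non-finite"
  )
  expect_true(is.finite(res$best_value))
})

test_that("config invariants are enforced", {
  expect_error(ngo_config(n = 1), "at least 2")
  expect_error(ngo_config(iterations = 0), "at least 1")
  expect_error(ngo_config(tau_levy = 2.5), "\\(0, 2\\]")
})

test_that("tidy, glance and autoplot expose the run", {
  res <- ngo_optimize(bench_problem("Sphere", 3),
                      ngo_config(n = 5, iterations = 10, seed = 1))
  td <- tidy(res)
  expect_equal(names(td), c("iteration", "best"))
  expect_equal(nrow(td), 10)
  gl <- glance(res)
  expect_equal(gl$best_value, res$best_value)
  expect_s3_class(autoplot(res), "ggplot")
})
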