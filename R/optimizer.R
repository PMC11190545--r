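# Northern Goshawk Optimization (NGO) and its Levy/chaos variant (NGO-LC).
#
# Both variants iterate two phases with greedy (elitist) acceptance:
#   1. prey identification (exploration): each individual picks a random
#      "prey" individual and moves toward it (if the prey is fitter) or
#      away from it (otherwise), with a per-dimension random step — a
#      per-dimension uniform(0,1) draw in baseline NGO, a per-individual
#      heavy-tailed Mantegna Levy draw in NGO-LC;
#   2. pursuit (exploitation): a multiplicative local perturbation
#      z + R (2r - 1) z, whose radius R shrinks linearly from 0.02 to 0
#      in baseline NGO and is replaced by the chaotic-map state in NGO-LC.
# Candidates are clipped to the box and replace the incumbent only on
# strict improvement, so the population best is non-increasing.

#' Optimizer run configuration
#'
#' @param n Population size (default 100).
#' @param iterations Number of iterations T (default 900).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param variant `"ngo-lc"` (default) or `"ngo"` (baseline).
#' @param tau_levy Levy constant for the exploration step (default 1.5).
#' @param chaos_floor Re-seed threshold for the chaotic radius
#'   (default 1e-12).
#' @param chaos_reseed Re-seed the chaotic radius when it collapses below
#'   `chaos_floor`? Default `TRUE`; without it the map reaches its fixed
#'   point 0 within a few iterations and exploitation stalls.
#' @param chaos_per_individual Keep one chaotic state per individual
#'   instead of one per run? Default `FALSE` (one state, advanced once per
#'   iteration).
#' @return A list of class `ngo_config`.
#' @export
ngo_config <- function(n = 100L, iterations = 900L, seed = NULL,
                       variant = c("ngo-lc", "ngo"), tau_levy = 1.5,
                       chaos_floor = 1e-12, chaos_reseed = TRUE,
                       chaos_per_individual = FALSE) {
  variant <- match.arg(variant)
  if (n < 2) rlang::abort("Population size `n` must be at least 2.")
  if (iterations < 1) rlang::abort("`iterations` must be at least 1.")
  if (tau_levy <= 0 || tau_levy > 2) {
    rlang::abort("`tau_levy` must lie in (0, 2].")
  }
  structure(
    list(n = as.integer(n), iterations = as.integer(iterations),
         seed = seed, variant = variant, tau_levy = tau_levy,
         chaos_floor = chaos_floor, chaos_reseed = isTRUE(chaos_reseed),
         chaos_per_individual = isTRUE(chaos_per_individual)),
    class = "ngo_config"
  )
}

resolve_objective <- function(objective, lower, upper) {
  if (inherits(objective, "bench_problem")) {
    p <- objective
    f <- if (p$noisy) {
      function(Z) bench_evaluate(p, Z, noise = "rng")
    } else {
      p$fn_matrix
    }
    list(f = f, lower = p$lower, upper = p$upper)
  } else {
    stopifnot(is.function(objective), length(lower) == length(upper),
              all(lower < upper))
    list(f = objective, lower = lower, upper = upper)
  }
}

#' Wrap a per-vector objective for the optimizer
#'
#' [ngo_optimize()] evaluates whole populations at once, so its objective
#' takes an N x m matrix and returns N values. This helper adapts an
#' ordinary vector-to-scalar function.
#'
#' @param f A function taking an m-vector and returning a scalar.
#' @return A function taking an N x m matrix and returning an N-vector.
#' @export
matrix_objective <- function(f) {
  function(Z) apply(Z, 1L, f)
}

clip_rows <- function(Z, lower, upper) {
  Z <- pmax(Z, matrix(lower, nrow(Z), ncol(Z), byrow = TRUE))
  pmin(Z, matrix(upper, nrow(Z), ncol(Z), byrow = TRUE))
}

#' Initialize an optimizer population
#'
#' Rows are drawn i.i.d. uniform within the box and evaluated.
#'
#' @param objective A [bench_problem()] or a matrix objective (see
#'   [matrix_objective()]).
#' @param n Population size (>= 2: exploration needs a distinct prey).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param lower,upper Bounds (ignored when `objective` is a
#'   `bench_problem`).
#' @return A list with `Z` (n x m positions) and `P` (length-n fitness).
#' @export
ngo_init_population <- function(objective, n, seed = NULL,
                                lower = NULL, upper = NULL) {
  if (n < 2) rlang::abort("Population size `n` must be at least 2.")
  ob <- resolve_objective(objective, lower, upper)
  m <- length(ob$lower)
  draw <- function() {
    Z <- matrix(stats::runif(n * m), n, m)
    Z <- sweep(sweep(Z, 2L, ob$upper - ob$lower, `*`), 2L, ob$lower, `+`)
    list(Z = Z, P = as.numeric(ob$f(Z)))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Pure candidate formulas, exposed for hand-computation tests. ----------

#' Exploration-phase candidate (prey identification)
#'
#' `z + step * (prey - I z)` when the prey is strictly fitter, else
#' `z + step * (z - prey)`; all arguments vectorize over dimensions.
#'
#' @param z,prey Current and prey positions.
#' @param step Per-dimension step multiplier (uniform or Levy draw).
#' @param I Intensity factor, 1 or 2 (one draw per individual).
#' @param prey_better Logical: prey fitness strictly below the
#'   individual's?
#' @return Candidate position (not yet clipped to bounds).
#' @export
ngo_explore_candidate <- function(z, prey, step, I, prey_better) {
  if (isTRUE(prey_better)) z + step * (prey - I * z) else z + step * (z - prey)
}

#' Exploitation-phase candidate (pursuit)
#'
#' `z + radius * (2 r - 1) * z` with a per-dimension uniform draw `r`.
#'
#' @param z Current position.
#' @param radius Pursuit radius: `0.02 (1 - t/T)` in baseline NGO, the
#'   chaotic-map state in NGO-LC.
#' @param r Per-dimension uniform(0, 1) draw.
#' @return Candidate position (not yet clipped to bounds).
#' @export
ngo_exploit_candidate <- function(z, radius, r) {
  z + radius * (2 * r - 1) * z
}

#' Baseline pursuit radius schedule
#'
#' @param t Iteration index, 0-based.
#' @param iterations Total iteration count T.
#' @return `0.02 * (1 - t / T)`.
#' @export
ngo_radius <- function(t, iterations) 0.02 * (1 - t / iterations)

#' One full optimizer iteration
#'
#' Applies the exploration pass to every individual (synchronously,
#' against the population as it stood at the start of the pass), then the
#' exploitation pass. Random draws can be injected through `draws` for
#' exact reproduction; when `draws` is `NULL` they are generated from the
#' current RNG stream in the documented order (prey indices, intensity
#' factors, exploration step matrix, exploitation uniform matrix).
#'
#' @param Z n x m position matrix.
#' @param P Length-n fitness vector (`objective` values of `Z` rows).
#' @param objective Matrix objective (N x m -> N).
#' @param lower,upper Box bounds (length m).
#' @param t 0-based iteration index.
#' @param iterations Total iterations T.
#' @param variant `"ngo"` or `"ngo-lc"`.
#' @param gamma Chaotic radius state (scalar or length-n), used by
#'   `"ngo-lc"` only.
#' @param tau_levy Levy constant for `"ngo-lc"` exploration steps.
#' @param draws Optional injected draws: a list with `k` (prey indices,
#'   excluding self), `I` (1/2 per individual), `step` (n x m exploration
#'   multipliers) and `r2` (n x m exploitation uniforms).
#' @return List with updated `Z`, `P`, and `n_nonfinite` (count of
#'   rejected non-finite candidate evaluations).
#' @export
ngo_iteration <- function(Z, P, objective, lower, upper, t, iterations,
                          variant = "ngo-lc", gamma = NULL, tau_levy = 1.5,
                          draws = NULL) {
  n <- nrow(Z); m <- ncol(Z)
  if (is.null(draws)) {
    u <- sample.int(n - 1L, n, replace = TRUE)
    k <- u + (u >= seq_len(n))
    I <- sample.int(2L, n, replace = TRUE)
    step <- if (variant == "ngo-lc") {
      # one scalar Levy factor per individual per update: Fl(alpha) in the
      # exploration move carries no dimension subscript, and a shared
      # factor preserves the toward-prey line search that drives
      # convergence (an independent heavy-tailed draw per coordinate
      # scrambles the move direction and stalls the algorithm)
      matrix(levy_step(n, tau_levy), n, m)
    } else {
      matrix(stats::runif(n * m), n, m)
    }
    r2 <- matrix(stats::runif(n * m), n, m)
    draws <- list(k = k, I = I, step = step, r2 = r2)
  }
  nonfinite <- 0L

  # exploration: prey taken from the phase-entry population snapshot
  prey <- Z[draws$k, , drop = FALSE]
  toward <- P[draws$k] < P
  Imat <- matrix(draws$I, n, m)
  cand <- ifelse(matrix(toward, n, m),
                 Z + draws$step * (prey - Imat * Z),
                 Z + draws$step * (Z - prey))
  cand <- clip_rows(cand, lower, upper)
  Pc <- as.numeric(objective(cand))
  bad <- !is.finite(Pc)
  if (any(bad)) { nonfinite <- nonfinite + sum(bad); Pc[bad] <- Inf }
  acc <- Pc < P
  Z[acc, ] <- cand[acc, , drop = FALSE]
  P[acc] <- Pc[acc]

  # exploitation
  radius <- if (variant == "ngo-lc") {
    if (is.null(gamma)) rlang::abort("NGO-LC needs a chaotic state `gamma`.")
    matrix(gamma, n, m)
  } else {
    ngo_radius(t, iterations)
  }
  cand <- Z + radius * (2 * draws$r2 - 1) * Z
  cand <- clip_rows(cand, lower, upper)
  Pc <- as.numeric(objective(cand))
  bad <- !is.finite(Pc)
  if (any(bad)) { nonfinite <- nonfinite + sum(bad); Pc[bad] <- Inf }
  acc <- Pc < P
  Z[acc, ] <- cand[acc, , drop = FALSE]
  P[acc] <- Pc[acc]

  list(Z = Z, P = P, n_nonfinite = nonfinite)
}

#' Run the NGO or NGO-LC optimizer
#'
#' Minimizes `objective` over a box. Per iteration every individual
#' undergoes the exploration step then the exploitation step, each with
#' greedy acceptance, so the returned best-so-far history is
#' non-increasing. For `"ngo-lc"` the chaotic radius is initialized to a
#' uniform(0, 1) draw and advanced once per iteration (once per
#' individual with `chaos_per_individual = TRUE`).
#'
#' @param objective A [bench_problem()] (bounds taken from it; Quartic
#'   noise drawn per evaluation) or a matrix objective `N x m -> N` (see
#'   [matrix_objective()]).
#' @param config An [ngo_config()].
#' @param lower,upper Bounds, required when `objective` is a bare
#'   function.
#' @return An object of class `ngo_result`: `best_position`,
#'   `best_value`, `history` (best-so-far after each iteration, length
#'   T), `n_evaluations`, `variant`, `config`.
#' @export
#' @examples
#' p <- bench_problem("Sphere", 5)
#' res <- ngo_optimize(p, ngo_config(n = 20, iterations = 50, seed = 1))
#' res$best_value
ngo_optimize <- function(objective, config = ngo_config(),
                         lower = NULL, upper = NULL) {
  ob <- resolve_objective(objective, lower, upper)
  run <- function() {
    pop <- ngo_init_population_raw(ob, config$n)
    Z <- pop$Z; P <- pop$P
    n_eval <- config$n
    nonfinite <- 0L
    T_ <- config$iterations
    gamma <- if (config$variant == "ngo-lc") {
      if (config$chaos_per_individual) stats::runif(config$n) else stats::runif(1)
    }
    history <- numeric(T_)
    for (t in seq_len(T_) - 1L) {
      it <- ngo_iteration(Z, P, ob$f, ob$lower, ob$upper, t, T_,
                          variant = config$variant, gamma = gamma,
                          tau_levy = config$tau_levy)
      Z <- it$Z; P <- it$P
      nonfinite <- nonfinite + it$n_nonfinite
      n_eval <- n_eval + 2L * config$n
      history[t + 1L] <- min(P)
      if (config$variant == "ngo-lc") {
        gamma <- chaos_next(gamma, floor = config$chaos_floor,
                            reseed = config$chaos_reseed)
      }
    }
    if (nonfinite > 0L) {
      rlang::warn(sprintf(
        "%d candidate(s) evaluated non-finite and were rejected.", nonfinite))
    }
    i <- which.min(P)
    structure(
      list(best_position = Z[i, ], best_value = P[i], history = history,
           n_evaluations = n_eval, variant = config$variant, config = config),
      class = "ngo_result"
    )
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

# init against an already-resolved objective, using the current RNG stream
ngo_init_population_raw <- function(ob, n) {
  m <- length(ob$lower)
  Z <- matrix(stats::runif(n * m), n, m)
  Z <- sweep(sweep(Z, 2L, ob$upper - ob$lower, `*`), 2L, ob$lower, `+`)
  P <- as.numeric(ob$f(Z))
  P[!is.finite(P)] <- Inf
  list(Z = Z, P = P)
}

#' @export
print.ngo_result <- function(x, ...) {
  cat(sprintf(
    "<ngo_result> %s  best = %.6g  (%d iterations, %d evaluations)\n",
    toupper(x$variant), x$best_value, length(x$history), x$n_evaluations))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an optimizer run into its convergence history
#'
#' @param x An `ngo_result`.
#' @param ... Unused.
#' @return A tibble with `iteration` (1-based) and `best` (best-so-far
#'   objective value).
#' @method tidy ngo_result
#' @export
tidy.ngo_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$history), best = x$history)
}

#' One-row summary of an optimizer run
#'
#' @param x An `ngo_result`.
#' @param ... Unused.
#' @return A one-row tibble: `variant`, `best_value`, `iterations`,
#'   `pop_size`, `n_evaluations`.
#' @method glance ngo_result
#' @export
glance.ngo_result <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, best_value = x$best_value,
    iterations = length(x$history), pop_size = x$config$n,
    n_evaluations = x$n_evaluations
  )
}

#' Convergence plot for an optimizer run
#'
#' @param object An `ngo_result`.
#' @param ... Unused.
#' @return A ggplot: best-so-far objective value against iteration, on a
#'   log10 y axis when all values are positive.
#' @method autoplot ngo_result
#' @export
autoplot.ngo_result <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$best)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::labs(x = "Iteration", y = "Best objective value",
                  title = sprintf("%s convergence", toupper(object$variant)))
  if (all(d$best > 0)) p <- p + ggplot2::scale_y_log10()
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
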