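#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Registry of the twelve analytic validation objectives. Each entry carries
# the box bounds, the known optimum and two evaluators: one for a single
# position vector and one for an N x d population matrix (row-wise), which
# the optimizer uses to keep an iteration a handful of matrix operations.
#
# All functions attain their minimum value 0. The Step function here is the
# continuous variant sum((x + 0.5)^2), so its optimum sits at -0.5 * 1, not
# at the origin; Rosenbrock's optimum is the all-ones vector. Quartic adds
# uniform(0, 1) observation noise per evaluation; with the noise source
# disabled its value at the origin is exactly 0.
bench_registry <- function() {
  list(
    "Sphere" = list(
      lower = -100, upper = 100, opt = 0,
      fm = function(Z) rowSums(Z^2)
    ),
    "Schwefel 1.2" = list(
      lower = -100, upper = 100, opt = 0,
      # cumulative-sum form of sum_i (sum_{j<=i} x_j)^2
      fm = function(Z) {
        C <- t(apply(Z, 1L, cumsum))
        if (ncol(Z) == 1L) C <- t(C)
        rowSums(C^2)
      }
    ),
    "Schwefel 2.20" = list(
      lower = -100, upper = 100, opt = 0,
      fm = function(Z) rowSums(abs(Z))
    ),
    "Schwefel 2.21" = list(
      lower = -100, upper = 100, opt = 0,
      fm = function(Z) apply(abs(Z), 1L, max)
    ),
    "Schwefel 2.22" = list(
      lower = -10, upper = 10, opt = 0,
      fm = function(Z) rowSums(abs(Z)) + apply(abs(Z), 1L, prod)
    ),
    "Schwefel 2.23" = list(
      lower = -10, upper = 10, opt = 0,
      fm = function(Z) rowSums(Z^10)
    ),
    "Rosenbrock" = list(
      lower = -30, upper = 30, opt = 1,
      fm = function(Z) {
        d <- ncol(Z)
        if (d < 2L) return(rep(0, nrow(Z)))
        A <- Z[, -1L, drop = FALSE]
        B <- Z[, -d, drop = FALSE]
        rowSums(100 * (A - B^2)^2 + (B - 1)^2)
      }
    ),
    "Step" = list(
      lower = -100, upper = 100, opt = -0.5,
      fm = function(Z) rowSums((Z + 0.5)^2)
    ),
    "Sum Squares" = list(
      lower = -10, upper = 10, opt = 0,
      fm = function(Z) {
        i <- seq_len(ncol(Z))
        drop(Z^2 %*% i)
      }
    ),
    "Zakharov" = list(
      lower = -5, upper = 10, opt = 0,
      fm = function(Z) {
        i <- seq_len(ncol(Z))
        s <- drop(Z %*% (0.5 * i))
        rowSums(Z^2) + s^2 + s^4
      }
    ),
    "Quartic" = list(
      lower = -1.28, upper = 1.28, opt = 0, noisy = TRUE,
      fm = function(Z) rowSums(Z^4)
    ),
    "Powell sum" = list(
      lower = -1, upper = 1, opt = 0,
      fm = function(Z) {
        p <- seq_len(ncol(Z)) + 1
        rowSums(sweep(abs(Z), 2L, p, `^`))
      }
    )
  )
}

#' Names of the twelve benchmark objectives
#'
#' Returns the registry names in canonical suite order (Sphere first,
#' Powell sum last), the order used by [benchmark_suite()] summaries.
#'
#' @return Character vector of length 12.
#' @export
#' @examples
#' bench_names()
bench_names <- function() names(bench_registry())

#' Construct a benchmark problem
#'
#' Builds one of the twelve analytic test objectives with its box bounds
#' and known optimum. Every objective has minimum value 0; the Quartic
#' objective adds uniform(0, 1) noise per evaluation unless the noise
#' source is disabled (see [bench_evaluate()]).
#'
#' @param name One of [bench_names()].
#' @param dimension Number of decision variables (default 30).
#' @return An object of class `bench_problem`: a list with `name`,
#'   `dimension`, `lower`, `upper` (per-coordinate bound vectors),
#'   `optimum_position`, `optimum_value`, `noisy`, and the evaluators
#'   `fn` (vector -> scalar) and `fn_matrix` (N x d matrix -> N vector).
#' @export
#' @examples
#' p <- bench_problem("Sphere", 30)
#' p$fn(rep(0, 30))
bench_problem <- function(name, dimension = 30L) {
  reg <- bench_registry()
  if (!is.character(name) || length(name) != 1L || !name %in% names(reg)) {
    abort(paste0(
      "Unknown benchmark function ", deparse(substitute(name)), ": '",
      paste(as.character(name), collapse = ", "),
      "'. Valid names: ", paste(names(reg), collapse = ", "), "."
    ))
  }
  if (!is.numeric(dimension) || length(dimension) != 1L || dimension < 1 ||
      dimension != as.integer(dimension)) {
    abort("`dimension` must be a positive integer.")
  }
  d <- as.integer(dimension)
  e <- reg[[name]]
  noisy <- isTRUE(e$noisy)
  fm <- e$fm
  structure(
    list(
      name = name,
      dimension = d,
      lower = rep(e$lower, d),
      upper = rep(e$upper, d),
      optimum_position = rep(e$opt, d),
      optimum_value = 0,
      noisy = noisy,
      fn = function(x) bench_evaluate_core(fm, rbind(x), d, noisy, NULL)[1L],
      fn_matrix = function(Z) bench_evaluate_core(fm, Z, d, noisy, NULL)
    ),
    class = "bench_problem"
  )
}

bench_evaluate_core <- function(fm, Z, d, noisy, noise) {
  if (!is.matrix(Z)) Z <- matrix(Z, nrow = 1L)
  if (ncol(Z) != d) {
    abort(sprintf("Position has %d coordinates; problem dimension is %d.",
                  ncol(Z), d))
  }
  v <- unname(fm(Z))
  if (noisy && !is.null(noise)) v <- v + noise(nrow(Z))
  v
}

#' Evaluate a benchmark problem at a position
#'
#' @param problem A [bench_problem()].
#' @param x Position vector of length `problem$dimension`, or an N x d
#'   matrix of positions (one per row).
#' @param noise Noise control for the Quartic objective: `NULL` (default)
#'   disables the additive uniform(0, 1) term so evaluation is
#'   deterministic; `"rng"` draws it from the current RNG stream (seed with
#'   [set.seed()] for reproducibility). Ignored by all other objectives.
#' @return Objective value(s): a scalar for a vector `x`, a vector for a
#'   matrix `x`.
#' @export
#' @examples
#' p <- bench_problem("Schwefel 2.22", 3)
#' bench_evaluate(p, c(1, -2, 3)) # 6 + 6 = 12
bench_evaluate <- function(problem, x, noise = NULL) {
  stopifnot(inherits(problem, "bench_problem"))
  noise_fn <- NULL
  if (!is.null(noise)) {
    if (identical(noise, "rng")) {
      noise_fn <- function(n) stats::runif(n)
    } else if (is.function(noise)) {
      noise_fn <- noise
    } else {
      abort("`noise` must be NULL, \"rng\", or a function(n) -> n draws.")
    }
  }
  reg <- bench_registry()
  fm <- reg[[problem$name]]$fm
  v <- bench_evaluate_core(fm, if (is.matrix(x)) x else rbind(x),
                           problem$dimension, problem$noisy, noise_fn)
  if (is.matrix(x)) v else v[1L]
}

#' Benchmark suite description table
#'
#' One row per objective in suite order, with dimension defaults and
#' bounds — a convenience view of the registry.
#'
#' @param dimension Dimension used to instantiate each problem.
#' @return A tibble with columns `function_name`, `dimension`, `lower`,
#'   `upper`, `optimum_value`, `noisy`.
#' @export
bench_table <- function(dimension = 30L) {
  purrr::map_dfr(bench_names(), function(nm) {
    p <- bench_problem(nm, dimension)
    tibble(
      function_name = nm, dimension = p$dimension,
      lower = p$lower[1L], upper = p$upper[1L],
      optimum_value = p$optimum_value, noisy = p$noisy
    )
  })
}

#' @export
print.bench_problem <- function(x, ...) {
  cat(sprintf(
    "<bench_problem> %s  d=%d  bounds=[%g, %g]  optimum=%g%s\n",
    x$name, x$dimension, x$lower[1L], x$upper[1L], x$optimum_value,
    if (x$noisy) "  (+ uniform noise)" else ""
  ))
  invisible(x)
}
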