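# Heavy-tailed step sampling (Mantegna scheme) and the chaotic radius map.

#' Mantegna scale parameter for Levy-flight steps
#'
#' Closed-form standard deviation sigma of the numerator normal in the
#' Mantegna scheme,
#' \deqn{\sigma = \left[\frac{\Gamma(1+\tau)\,\sin(\pi\tau/2)}
#'   {\Gamma((1+\tau)/2)\,\tau\,2^{(\tau-1)/2}}\right]^{1/\tau},}
#' where `tau` is the Levy stability constant. At `tau = 1` the expression
#' collapses to 1; the suite default is `tau = 1.5`.
#'
#' @param tau Levy constant, in (0, 2].
#' @return The scale sigma (a positive scalar).
#' @export
#' @examples
#' levy_sigma(1.5) # ~0.6966
levy_sigma <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) ||
      tau <= 0 || tau > 2) {
    rlang::abort("`tau` must be a single number in (0, 2].")
  }
  (gamma(1 + tau) * sin(pi * tau / 2) /
     (gamma((1 + tau) / 2) * tau * 2^((tau - 1) / 2)))^(1 / tau)
}

#' One or more Levy-flight steps (Mantegna algorithm)
#'
#' Draws steps `A / |B|^(1/tau)` with `A ~ N(0, sigma^2)`,
#' `B ~ N(0, 1)` and sigma from [levy_sigma()]. A `B` that underflows to
#' exactly zero is redrawn, so the quotient is always finite. Draws come
#' from the current RNG stream; seed with [set.seed()].
#'
#' @param n Number of steps.
#' @param tau Levy constant in (0, 2] (default 1.5).
#' @return Numeric vector of length `n`; heavy-tailed, symmetric about 0.
#' @export
levy_step <- function(n, tau = 1.5) {
  sig <- levy_sigma(tau)
  A <- stats::rnorm(n, sd = sig)
  B <- stats::rnorm(n)
  while (any(B == 0)) B[B == 0] <- stats::rnorm(sum(B == 0))
  levy_step_from_normals(A, B, tau)
}

# Deterministic core: the Mantegna quotient for injected normal draws.
# Exposed for oracle tests.
#' @rdname levy_step
#' @param A,B Injected normal draws (same length); `A` is assumed already
#'   scaled by sigma.
#' @export
levy_step_from_normals <- function(A, B, tau = 1.5) {
  stopifnot(length(A) == length(B), all(B != 0))
  A / abs(B)^(1 / tau)
}

#' Advance the chaotic radius map
#'
#' Iterates \eqn{\gamma_{i+1} = \gamma_i^2 \sin(\pi \gamma_i)} on [0, 1].
#' The map's only attracting fixed point is 0, which it reaches within a
#' few iterations from almost any start; with `reseed = TRUE` (the
#' default) a value falling below `floor` is replaced by a fresh
#' uniform(0, 1) draw from the current RNG stream, keeping the
#' exploitation radius alive for the whole run.
#'
#' @param gamma Current state in [0, 1].
#' @param floor Re-seed threshold (default 1e-12).
#' @param reseed Replace sub-floor values by a fresh uniform draw?
#' @return The next state in [0, 1].
#' @export
#' @examples
#' chaos_next(0.5, reseed = FALSE) # 0.25
chaos_next <- function(gamma, floor = 1e-12, reseed = TRUE) {
  if (!is.numeric(gamma) || any(!is.finite(gamma)) ||
      any(gamma < 0) || any(gamma > 1)) {
    rlang::abort("`gamma` must lie in [0, 1].")
  }
  g <- gamma^2 * sin(pi * gamma)
  # sin() rounding can leave a tiny negative at gamma = 1
  g <- pmin(pmax(g, 0), 1)
  if (reseed) {
    low <- g < floor
    if (any(low)) g[low] <- stats::runif(sum(low))
  }
  g
}
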