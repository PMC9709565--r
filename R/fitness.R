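#' Terminal fitness of a developmental outcome
#'
#' Evaluates the normalized power-family fitness landscape
#' \eqn{f(k) = (k/T)^\alpha} at `k` environment-matching increments out of a
#' horizon of `T`. Only increments matching the true environment count toward
#' `k`; fitness is awarded once, at the end of development. By construction
#' `f(0) = 0`, `f(T) = 1` and `f` is strictly increasing; the sign of its
#' second differences over `k = 0..T` is fixed by the curvature class of
#' `spec`.
#'
#' @param k Number of matching increments, integer(s) in `0..T`. Vectorized.
#' @param T Developmental horizon.
#' @param spec A [fitness_spec()].
#' @return Fitness value(s) in `[0, 1]`.
#' @examples
#' fitness_value(10, 20, fitness_spec("linear"))    # 0.5
#' fitness_value(10, 20, fitness_spec("convex"))    # 0.25
#' @export
fitness_value <- function(k, T, spec) {
  if (!inherits(spec, "fitness_spec")) {
    stop("`spec` must be a fitness_spec object")
  }
  if (any(k < 0 | k > T | k != round(k))) {
    stop(sprintf("`k` must be an integer in 0..%d", T))
  }
  (k / T)^spec$alpha
}

# fitness over the whole outcome grid k = 0..T; fails fast on non-finite values
fitness_grid <- function(T, spec) {
  f <- fitness_value(0:T, T, spec)
  if (any(!is.finite(f))) stop("non-finite fitness values on the outcome grid")
  f
}
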