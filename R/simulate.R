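#' Simulate a population developing under the optimal policy
#'
#' Forward Monte-Carlo simulation of `N` individuals in a fixed true
#' environment. Each timestep an individual draws a cue (c0 with probability
#' `q` in E0, `1 - q` in E1, i.i.d. given the environment), updates its
#' belief, and takes the policy's action at its current `(t, n0, x)` state;
#' tied states are resolved by a fair coin flip.
#'
#' Each individual consumes its own RNG substream, seeded from the master
#' seed via one reproducible draw per individual, so enlarging `N` leaves
#' the trajectories of the first individuals unchanged and identical
#' seed + configuration reproduce the result bit for bit.
#'
#' @param config A [model_config()]; `N`, `true_env` and `seed` govern the
#'   simulation.
#' @param solution The [solve_policy()] result for the same
#'   `(T, q, prior_p0, fitness)`; a mismatch is an error.
#' @return An object of class `population_result` holding, as `N x T`
#'   matrices, the cues (`1` = c0), posteriors and actions (`1` = y0,
#'   `0` = y1), the `N x (T + 1)` path of `n0`, and `terminal_n0`.
#' @seealso [individual_trajectory()], [empirical_mean_path()],
#'   [phase_diagram()], [distribution_summary()]
#' @export
simulate_population <- function(config, solution) {
  stopifnot(inherits(config, "model_config"), inherits(solution, "dp_solution"))
  sc <- solution$config
  if (sc$T != config$T || sc$q != config$q || sc$prior_p0 != config$prior_p0 ||
      !identical(unclass(sc$fitness), unclass(config$fitness))) {
    stop("config/policy mismatch: the solution was solved for different (T, q, prior_p0, fitness)")
  }
  Tb <- config$T
  N <- config$N

  # per-individual substreams: the first k seeds are identical for any N >= k
  set.seed(config$seed)
  ind_seeds <- sample.int(.Machine$integer.max, N)
  cue_u <- matrix(0, N, Tb)
  tie_u <- matrix(0, N, Tb)
  for (i in seq_len(N)) {
    set.seed(ind_seeds[i])
    u <- stats::runif(2L * Tb)
    cue_u[i, ] <- u[1:Tb]
    tie_u[i, ] <- u[(Tb + 1):(2L * Tb)]
  }

  p_c0 <- if (config$true_env == "E0") config$q else 1 - config$q
  cues <- matrix(as.integer(cue_u < p_c0), N, Tb)

  posteriors <- matrix(NA_real_, N, Tb)
  actions <- matrix(NA_integer_, N, Tb)
  n0_path <- matrix(0L, N, Tb + 1L)
  x <- integer(N)
  n0 <- integer(N)
  for (t in 1:Tb) {
    x <- x + cues[, t]
    posteriors[, t] <- solution$posterior[[t]][x + 1L]
    d <- solution$delta[[t]][cbind(n0 + 1L, x + 1L)]
    a <- integer(N)
    a[d > TIE_TOL] <- 1L
    tie <- abs(d) <= TIE_TOL
    a[tie] <- as.integer(tie_u[tie, t] < 0.5)
    actions[, t] <- a
    n0 <- n0 + a
    n0_path[, t + 1L] <- n0
  }

  structure(
    list(config = config, true_env = config$true_env, cues = cues,
         posteriors = posteriors, actions = actions, n0_path = n0_path,
         terminal_n0 = n0),
    class = "population_result"
  )
}

#' @export
print.population_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "simulated population: N = %d in %s, T = %d, q = %g, %s fitness\n",
    cfg$N, x$true_env, cfg$T, cfg$q, cfg$fitness$shape))
  cat(sprintf("  terminal n0: mean %.2f, sd %.2f, range %d..%d\n",
              mean(x$terminal_n0), stats::sd(x$terminal_n0),
              min(x$terminal_n0), max(x$terminal_n0)))
  invisible(x)
}

#' Extract one individual's developmental trajectory
#'
#' @param result A [simulate_population()] result.
#' @param i Individual index in `1..N`.
#' @return A data frame with one row per timestep: `t`, `cue`, `posterior`,
#'   `action`, and the specialization state `(n0, n1)` after the action.
#' @export
individual_trajectory <- function(result, i) {
  stopifnot(inherits(result, "population_result"))
  Tb <- result$config$T
  if (length(i) != 1L || i < 1 || i > result$config$N) {
    stop("`i` must index one simulated individual")
  }
  data.frame(
    t = 1:Tb,
    cue = c("c1", "c0")[result$cues[i, ] + 1L],
    posterior = result$posteriors[i, ],
    action = c("y1", "y0")[result$actions[i, ] + 1L],
    n0 = result$n0_path[i, -1L],
    n1 = 1:Tb - result$n0_path[i, -1L]
  )
}

#' Mean phenotypic path of a population
#'
#' Coordinate-wise mean specialization state through development (the black
#' mean-trajectory line of the phase diagrams). `mean_n1` is computed as
#' `t - mean_n0`, which the per-individual identity `n0 + n1 = t` makes
#' exact.
#'
#' @param result A [simulate_population()] result.
#' @return A data frame with columns `t` (0..T), `mean_n0`, `mean_n1`.
#' @export
empirical_mean_path <- function(result) {
  stopifnot(inherits(result, "population_result"))
  Tb <- result$config$T
  m0 <- colMeans(result$n0_path)
  data.frame(t = 0:Tb, mean_n0 = m0, mean_n1 = 0:Tb - m0)
}
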