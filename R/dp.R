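# value margin below which the two actions are declared tied
TIE_TOL <- 1e-12

#' Solve for the optimal developmental policy by backward induction
#'
#' Computes the exact optimal policy of the finite-horizon decision problem:
#' at each decision epoch `t = 1..T` the individual has observed `t` cues
#' (`x` of them c0; the cue of a timestep precedes its choice) and has made
#' `t - 1` increments (`n0` of them toward y0), and must choose its next
#' increment. Beliefs are indexed exactly by the sufficient statistic
#' `(t, x)` — never by discretized posterior values — so the state space is
#' the integer grid `(t, n0, x)` with `n0` in `0..t-1` and `x` in `0..t`.
#'
#' Terminal payoff after the last decision is the expected fitness
#' \eqn{W(n_0, x) = p_0(T, x) f(n_0) + (1 - p_0(T, x)) f(T - n_0)}, and for
#' `t < T` the value of an action is the expectation of the next epoch's
#' value over the predictive cue distribution at the current belief. The
#' returned root value is the expected terminal fitness of an optimal
#' individual before its first cue.
#'
#' @param config A [model_config()]; the solver is deterministic and ignores
#'   `N`, `true_env` and `seed`.
#' @return An object of class `dp_solution`: per-epoch value matrices `V`,
#'   value margins `delta` (value of choosing y0 minus value of choosing y1),
#'   action codes `action` (+1 y0, -1 y1, 0 tie, i.e. `|delta| <= 1e-12`),
#'   posteriors `posterior`, and `root_value`.
#' @seealso [policy_table()], [value_table()], [optimal_action()],
#'   [expectimax_oracle()]
#' @examples
#' sol <- solve_policy(model_config(T = 5))
#' sol$root_value
#' @export
solve_policy <- function(config) {
  stopifnot(inherits(config, "model_config"))
  Tb <- config$T
  q <- config$q
  f <- fitness_grid(Tb, config$fitness)           # f[k + 1] = f(k)
  p0 <- lapply(1:Tb, function(t) {
    posterior_from_counts(t, 0:t, q, config$prior_p0)
  })

  V <- vector("list", Tb)
  delta <- vector("list", Tb)
  for (t in Tb:1) {
    pt <- p0[[t]]                                  # length t + 1, over x = 0..t
    if (t == Tb) {
      # last decision: value of an action is the terminal expected fitness
      PT <- matrix(pt, nrow = t, ncol = t + 1, byrow = TRUE)
      n0 <- 0:(t - 1)
      vy0 <- PT * f[n0 + 2] + (1 - PT) * f[Tb - n0]      # ends at (n0+1, x)
      vy1 <- PT * f[n0 + 1] + (1 - PT) * f[Tb - n0 + 1]  # ends at (n0,   x)
    } else {
      # expectation of the next epoch's value over the predictive cue draw
      pc <- cue_predictive(pt, q)
      PC <- matrix(pc, nrow = t, ncol = t + 1, byrow = TRUE)
      Vn <- V[[t + 1]]                             # (t+1) x (t+2)
      A <- Vn[2:(t + 1), , drop = FALSE]           # rows for n0 + 1 (chose y0)
      B <- Vn[1:t, , drop = FALSE]                 # rows for n0     (chose y1)
      vy0 <- PC * A[, 2:(t + 2), drop = FALSE] + (1 - PC) * A[, 1:(t + 1), drop = FALSE]
      vy1 <- PC * B[, 2:(t + 2), drop = FALSE] + (1 - PC) * B[, 1:(t + 1), drop = FALSE]
    }
    V[[t]] <- pmax(vy0, vy1)
    delta[[t]] <- vy0 - vy1
  }
  action <- lapply(delta, function(d) {
    a <- matrix(0L, nrow(d), ncol(d))
    a[d > TIE_TOL] <- 1L
    a[d < -TIE_TOL] <- -1L
    a
  })
  pc1 <- cue_predictive(config$prior_p0, q)
  root <- pc1 * V[[1]][1, 2] + (1 - pc1) * V[[1]][1, 1]
  structure(
    list(config = config, V = V, delta = delta, action = action,
         posterior = p0, root_value = root),
    class = "dp_solution"
  )
}

#' @export
print.dp_solution <- function(x, ...) {
  cfg <- x$config
  n_states <- sum(vapply(1:cfg$T, function(t) t * (t + 1), numeric(1)))
  cat(sprintf(
    "optimal developmental policy: T = %d, q = %g, %s fitness (alpha = %g)\n",
    cfg$T, cfg$q, cfg$fitness$shape, cfg$fitness$alpha))
  cat(sprintf("  states: %d   root value: %.6f   ties: %d\n",
              n_states, x$root_value,
              sum(vapply(x$action, function(a) sum(a == 0L), numeric(1)))))
  invisible(x)
}

# long-format state index, ordered (t, then n0, then x)
state_frame <- function(Tb) {
  do.call(rbind, lapply(1:Tb, function(t) {
    data.frame(t = t,
               n0 = rep(0:(t - 1), each = t + 1),
               x = rep(0:t, times = t))
  }))
}

#' Policy table as a data frame
#'
#' Flattens the solved policy into one row per state `(t, n0, x)` in
#' deterministic order (`t`, then `n0`, then `x`), with the posterior at that
#' state, the value margin `delta` of choosing y0 over y1, and the action
#' (`"y0"`, `"y1"` or `"tie"`).
#'
#' @param solution A [solve_policy()] result.
#' @return A data frame with columns `t`, `n0`, `x`, `posterior`, `delta`,
#'   `action`; `sum(t * (t + 1))` rows (3080 for `T = 20`).
#' @export
policy_table <- function(solution) {
  stopifnot(inherits(solution, "dp_solution"))
  Tb <- solution$config$T
  df <- state_frame(Tb)
  df$posterior <- unlist(lapply(1:Tb, function(t) {
    rep(solution$posterior[[t]], times = t)
  }))
  df$delta <- unlist(lapply(solution$delta, function(m) as.vector(t(m))))
  acode <- unlist(lapply(solution$action, function(m) as.vector(t(m))))
  df$action <- c("y1", "tie", "y0")[acode + 2L]
  df
}

#' Value table as a data frame
#'
#' @param solution A [solve_policy()] result.
#' @return A data frame with columns `t`, `n0`, `x`, `value` in the same
#'   deterministic row order as [policy_table()].
#' @export
value_table <- function(solution) {
  stopifnot(inherits(solution, "dp_solution"))
  df <- state_frame(solution$config$T)
  df$value <- unlist(lapply(solution$V, function(m) as.vector(t(m))))
  df
}

#' Look up the optimal action at a state
#'
#' Returns the policy's action at `(t, n0, x)`. Ties (value margin within
#' `1e-12`) are not frozen into the policy but resolved at lookup time by a
#' fair coin flip on the current RNG stream, which preserves the model's
#' left/right symmetry under a flat prior.
#'
#' @param solution A [solve_policy()] result.
#' @param t Decision epoch in `1..T`.
#' @param n0 Increments toward y0 already made, in `0..t-1`.
#' @param x Number of c0 cues observed, in `0..t`.
#' @return `"y0"` or `"y1"`.
#' @export
optimal_action <- function(solution, t, n0, x) {
  stopifnot(inherits(solution, "dp_solution"))
  Tb <- solution$config$T
  if (length(t) != 1L || t < 1 || t > Tb || t != round(t)) {
    stop(sprintf("`t` must be an integer in 1..%d", Tb))
  }
  if (length(n0) != 1L || n0 < 0 || n0 > t - 1 || n0 != round(n0)) {
    stop(sprintf("`n0` must be an integer in 0..%d at epoch %d", t - 1, t))
  }
  if (length(x) != 1L || x < 0 || x > t || x != round(x)) {
    stop(sprintf("`x` must be an integer in 0..%d at epoch %d", t, t))
  }
  a <- solution$action[[t]][n0 + 1L, x + 1L]
  if (a == 0L) a <- if (stats::runif(1) < 0.5) 1L else -1L
  if (a == 1L) "y0" else "y1"
}

#' Myopic maximum-a-posteriori policy for linear fitness
#'
#' Under a linear fitness landscape the value of an increment decomposes
#' additively — by the martingale property of the posterior, a y0 increment
#' is worth `p0 / T` in expectation and a y1 increment `(1 - p0) / T` —
#' so simply specializing toward the currently more probable environment is
#' globally optimal and the accrued state `n0` is irrelevant: behaviour
#' affects state but state does not feed back on behaviour. This constructs
#' that greedy policy directly (action y0 where `p0 > 0.5`, y1 where
#' `p0 < 0.5`, tie at exactly 0.5); it must agree with [solve_policy()] at
#' every state and serves as an independent cross-check.
#'
#' @param config A [model_config()] with `fitness$shape == "linear"`.
#' @return An object of class `greedy_policy` with per-epoch `action`
#'   matrices coded like a `dp_solution`'s.
#' @export
greedy_map_policy <- function(config) {
  stopifnot(inherits(config, "model_config"))
  if (config$fitness$shape != "linear") {
    stop("greedy_map_policy() requires a linear fitness landscape")
  }
  Tb <- config$T
  p0 <- lapply(1:Tb, function(t) {
    posterior_from_counts(t, 0:t, config$q, config$prior_p0)
  })
  action <- lapply(1:Tb, function(t) {
    a <- ifelse(p0[[t]] > 0.5, 1L, ifelse(p0[[t]] < 0.5, -1L, 0L))
    matrix(rep(a, each = t), nrow = t, ncol = t + 1)
  })
  structure(list(config = config, action = action, posterior = p0),
            class = "greedy_policy")
}
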