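# Brute-force reference solvers. These deliberately share no arithmetic with
# solve_policy(): beliefs come from raw likelihood products over explicit cue
# sequences, and no (t, n0, x) state aggregation is used, so agreement with
# the backward-induction solver also certifies that (t, n0, x) is a
# sufficient statistic.

#' Full-history expectimax value (brute-force oracle)
#'
#' Enumerates the complete cue/action tree over explicit cue sequences:
#' at every history node the posterior is recomputed from the raw Bayes
#' product over the sequence, actions are maximized, and cues are averaged
#' under their exact predictive probability. No state aggregation is
#' performed, so the tree has \eqn{4^T} leaves; the horizon is capped at
#' `T <= 12`.
#'
#' @param config A [model_config()].
#' @return The root expected terminal fitness; must equal
#'   `solve_policy(config)$root_value` to within `1e-12`.
#' @export
expectimax_oracle <- function(config) {
  stopifnot(inherits(config, "model_config"))
  Tb <- config$T
  if (Tb > 12) stop("expectimax_oracle() enumerates 4^T nodes; T must be <= 12")
  q <- config$q
  prior <- config$prior_p0
  f <- fitness_value(0:Tb, Tb, config$fitness)

  # value at a node where `cues` (1 = c0) have been observed and the current
  # timestep's action is still pending; n0 = y0 increments already made
  node_value <- function(cues, n0) {
    l0 <- prod(ifelse(cues == 1L, q, 1 - q))      # P(sequence | E0)
    l1 <- prod(ifelse(cues == 1L, 1 - q, q))      # P(sequence | E1)
    post <- prior * l0 / (prior * l0 + (1 - prior) * l1)
    t <- length(cues)
    if (t == Tb) {
      vy0 <- post * f[n0 + 2] + (1 - post) * f[Tb - n0]
      vy1 <- post * f[n0 + 1] + (1 - post) * f[Tb - n0 + 1]
      return(max(vy0, vy1))
    }
    pc <- post * q + (1 - post) * (1 - q)
    vy0 <- pc * node_value(c(cues, 1L), n0 + 1L) +
      (1 - pc) * node_value(c(cues, 0L), n0 + 1L)
    vy1 <- pc * node_value(c(cues, 1L), n0) +
      (1 - pc) * node_value(c(cues, 0L), n0)
    max(vy0, vy1)
  }

  pc1 <- prior * q + (1 - prior) * (1 - q)
  pc1 * node_value(1L, 0L) + (1 - pc1) * node_value(0L, 0L)
}

#' Exhaustive search over all deterministic state policies (second oracle)
#'
#' Enumerates every mapping from the reachable states `(t, n0, x)` to
#' `{y0, y1}` as a bit vector, evaluates each policy by its exact expected
#' terminal fitness (summing over all `2^T` cue sequences weighted under both
#' environments), and returns the best value found. Independent of the
#' backward-induction recursion structure. The state space has
#' `sum(t * (t + 1))` cells, so `T = 3` already means `2^20` candidate
#' policies; the horizon is capped at `T <= 3`.
#'
#' @param config A [model_config()] with `T <= 3`.
#' @return The maximum expected terminal fitness over deterministic policies;
#'   must equal `solve_policy(config)$root_value` to within `1e-12`.
#' @export
exhaustive_policy_search <- function(config) {
  stopifnot(inherits(config, "model_config"))
  Tb <- config$T
  if (Tb > 3) stop("exhaustive_policy_search() requires T <= 3")
  q <- config$q
  prior <- config$prior_p0
  f <- fitness_value(0:Tb, Tb, config$fitness)

  sizes <- vapply(1:Tb, function(t) t * (t + 1), numeric(1))
  off <- c(0, cumsum(sizes))                       # bit offset of epoch t
  n_states <- off[Tb + 1]
  pols <- 0:(2^n_states - 1)                       # one integer per policy
  total <- numeric(length(pols))

  seqs <- as.matrix(expand.grid(rep(list(0:1), Tb)))
  for (s in seq_len(nrow(seqs))) {
    cues <- as.integer(seqs[s, ])
    l0 <- prod(ifelse(cues == 1L, q, 1 - q))
    l1 <- prod(ifelse(cues == 1L, 1 - q, q))
    x <- cumsum(cues)
    n0 <- integer(length(pols))                    # per-policy n0 so far
    for (t in 1:Tb) {
      bit_idx <- off[t] + n0 * (t + 1L) + x[t]     # state bit of each policy
      n0 <- n0 + bitwAnd(bitwShiftR(pols, bit_idx), 1L)
    }
    total <- total + prior * l0 * f[n0 + 1] + (1 - prior) * l1 * f[Tb - n0 + 1]
  }
  max(total)
}
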