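#' Posterior belief from cue counts
#'
#' Closed-form Bayesian posterior probability of environment E0 after
#' observing `t_cues` conditionally i.i.d. binary cues of which `x` were c0
#' (the cue associated with E0). Because cues are exchangeable the posterior
#' depends on the sequence only through `(t_cues, x)`; it is computed in the
#' numerically stable odds form
#' \deqn{p_0 = \frac{1}{1 + \frac{1-\pi}{\pi}\,r^{\,2x - t}}, \qquad
#'       r = \frac{1-q}{q},}
#' with \eqn{\pi} the prior, which avoids underflow of the raw likelihood
#' products at large `t`.
#'
#' @param t_cues Number of cues observed so far (non-negative integer).
#' @param x Number of c0 cues among them, `0 <= x <= t_cues`. Vectorized.
#' @param q Cue reliability in `[0.5, 1]`.
#' @param prior_p0 Prior probability of E0, in `(0, 1)`.
#' @return Posterior probability of E0, in `[0, 1]`. With `q = 0.5` the cues
#'   are uninformative and the prior is returned unchanged.
#' @examples
#' posterior_from_counts(4, 3, 0.55, 0.5)  # 0.599009900990099
#' @export
posterior_from_counts <- function(t_cues, x, q, prior_p0) {
  if (any(x < 0 | x > t_cues)) stop("`x` must satisfy 0 <= x <= t_cues")
  if (any(q < 0.5 | q > 1)) stop("`q` must lie in [0.5, 1]")
  if (any(prior_p0 <= 0 | prior_p0 >= 1)) stop("`prior_p0` must be in (0, 1)")
  r <- (1 - q) / q
  w <- r^(2 * x - t_cues)
  # this arrangement returns the prior bit-exactly when w = 1 (q = 0.5 or
  # balanced cues), since fl(p) + fl(1 - p) == 1
  prior_p0 / (prior_p0 + (1 - prior_p0) * w)
}

#' One-cue Bayesian update
#'
#' Updates a belief `p0` after a single imperfect cue: the likelihood of c0 is
#' `q` under E0 and `1 - q` under E1. Folding a cue sequence through this
#' update reproduces [posterior_from_counts()] on the sequence's counts.
#'
#' @param p0 Current probability of E0, in `[0, 1]`. Vectorized.
#' @param cue `"c0"` or `"c1"`.
#' @param q Cue reliability in `[0.5, 1]`.
#' @return Updated probability of E0.
#' @examples
#' sequential_update(0.5, "c0", 0.55)  # 0.55
#' @export
sequential_update <- function(p0, cue, q) {
  if (any(p0 < 0 | p0 > 1)) stop("`p0` must lie in [0, 1]")
  if (!all(cue %in% c("c0", "c1"))) stop("`cue` must be \"c0\" or \"c1\"")
  L <- ifelse(cue == "c0", q, 1 - q)
  num <- p0 * L
  num / (num + (1 - p0) * (1 - L))
}

#' Predictive probability of the next cue
#'
#' Marginal probability that the next cue is c0 given the current belief:
#' `p0 * q + (1 - p0) * (1 - q)`. This is the mixing weight used both by the
#' dynamic-programming recursion and by the forward simulator.
#'
#' @param p0 Current probability of E0, in `[0, 1]`. Vectorized.
#' @param q Cue reliability in `[0.5, 1]`.
#' @return Probability in `[1 - q, q]` that the next cue is c0.
#' @export
cue_predictive <- function(p0, q) {
  if (any(p0 < 0 | p0 > 1)) stop("`p0` must lie in [0, 1]")
  p0 * q + (1 - p0) * (1 - q)
}
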