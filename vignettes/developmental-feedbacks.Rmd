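---
title: "Methods: optimal incremental development and behaviour-state feedbacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optimal incremental development and behaviour-state feedbacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devfeedbacks)
```

## The model

An individual develops over a finite horizon of `T` timesteps in one of two
environmental conditions, E0 or E1, fixed for life but never observed
directly. Each timestep it first receives an imperfect binary cue — c0 with
probability `q` in E0 and `1 - q` in E1, conditionally i.i.d. — and then
commits an irreversible unit increment toward one of two phenotypic
specializations, y0 or y1. The individual's state is the pair
`(n0, n1)` of increments accrued in each direction; its informational state
is the Bayesian posterior probability `p0` of being in E0. Increments only
pay off if they match the environment: terminal fitness is
`f(k)` where `k` is the number of matching increments (`n0` in E0,
`n1 = T - n0` in E1) and

$$f(k) = (k/T)^{\alpha}.$$

The exponent spans the three curvature classes of interest: decelerating
returns to specialization (concave, `0 < alpha < 1`, default 0.5), constant
returns (linear, `alpha = 1`) and accelerating returns (convex, `alpha > 1`,
default 2). Fitness is normalized to `[0, 1]`; since the optimal policy is
invariant to positive affine rescaling of `f`, the normalization is a
convenience, not an assumption. Fitness accrues only at the end of
development; there are no intermediate payoffs.

Because cues are exchangeable, the belief depends on the history only
through the count pair `(t, x)` (cues seen, c0 cues among them):

$$p_0(t, x) = \frac{\pi}{\pi + (1-\pi)\, r^{\,2x-t}}, \qquad
  r = \frac{1-q}{q},$$

with `π` the prior. The solver and the simulator always evaluate beliefs
through this closed form; the one-cue update `sequential_update()` is
exposed for completeness and equals the closed form when folded over a
sequence (see *Numerical choices*).

## Exact policy by backward induction

At decision epoch `t` an individual has observed `t` cues and made `t - 1`
increments (within a timestep the cue precedes the choice), so the state
space is the integer grid `(t, n0, x)` with `n0` in `0..t-1`, `x` in
`0..t` — `sum(t (t+1)) = 3080` states at `T = 20`. `solve_policy()` fills
the value table backwards from the terminal payoff

$$W(n_0, x) = p_0(T, x)\, f(n_0) + (1 - p_0(T, x))\, f(T - n_0),$$

taking at each state the best action under the predictive cue distribution
`P(c0) = p0 q + (1 - p0)(1 - q)`. Beliefs are indexed by the exact counts,
never by discretized posterior values, so the recursion is exact up to
floating-point rounding. The policy stores the value margin
`delta = V(y0) - V(y1)` per state; `|delta| <= 1e-12` is declared a tie.
Ties are real, not numerical debris: with a flat prior and `q = 0.5` the
very first decision is exactly tied, and freezing a deterministic tie-break
into the policy would destroy the model's left/right symmetry. They are
therefore resolved by a fair coin at simulation time.

Two independent brute-force oracles guard the solver. `expectimax_oracle()`
enumerates the full cue/action tree over explicit sequences with no state
aggregation, recomputing every belief from raw likelihood products;
agreement (to 1e-12; observed 2e-16) also certifies that `(t, n0, x)` is a
sufficient statistic. `exhaustive_policy_search()` evaluates *every*
deterministic state-policy as a bit vector (`2^20` policies at `T = 3`) by
exact expectation over all cue sequences and both environments; it shares
no recursion structure with either of the others. Closed-form limits pin
the uninformative-cue case `q = 0.5`: the belief never leaves 1/2, ending
at `n0` is worth `(f(n0) + f(T - n0))/2`, so the root value is 0.5 for the
linear and convex landscapes and `(1/2)^{1/2} ≈ 0.7071` for the concave
default.

Under linear fitness the posterior-martingale property makes the problem
additive — a y0 increment is worth `p0/T` no matter what follows — so the
myopic rule "specialize toward the currently more probable environment" is
globally optimal, and `greedy_map_policy()` rebuilds it directly as an
independent cross-check of the DP at all 3080 states. This is also the
substantive point of the linear case: state does not feed back on
behaviour at all.

## Population simulation

`simulate_population()` develops `N` individuals forward under the solved
policy in a fixed true environment. Every individual has its own RNG
substream seeded by one reproducible draw from the master seed, so results
are bit-reproducible and enlarging `N` leaves earlier individuals'
trajectories unchanged. Each individual pre-draws `T` cue uniforms and `T`
tie-break uniforms, which fixes stream consumption independently of the
path taken. Cues are i.i.d. given the environment — no autocorrelation, no
between-individual interaction, no frequency dependence.

## Derived analyses

**Threshold curves.** The feedback sign lives in the decision threshold
`tau(n0)`: the minimum posterior at which a further y0 increment is
optimal, as a function of the y0 increments already accrued.
`threshold_curve_from_policy()` computes it exactly, aggregating over
decision epochs by the minimum and counting exact ties as "y0 optimal"
(ties take y0 with probability one half, so the tie posterior is the
boundary at which y0 enters the optimal action set; this also makes the
exact curve the large-`N` limit of the simulation estimator
`threshold_curve_from_simulation()`, which takes the minimum posterior
among observed y0 choices per `n0` level). Under linear fitness the curve
sits flat at exactly 0.5; a rising curve (concave) is a negative feedback,
a falling one (convex) positive. The un-aggregated per-epoch boundary is
exposed by `threshold_by_epoch()` for diagnostics.

One discretization subtlety is worth recording. The reachable posteriors
at epoch `t` lie on the odds grid `r^{2x-t}`, whose parity alternates with
`t`; the final specialization level `n0 = T - 1` is observable only at the
terminal epoch. For even `T` this produces isolated parity artifacts when
the minimum is taken across epochs — e.g. at `q = 0.9` under convex
fitness, the sunk-cost state `(t = 19, n0 = 18, x = 9)` makes a further y0
increment optimal at posterior 0.1, while the terminal epoch's grid skips
0.1 entirely, so the aggregated curve ticks back up at its final level (a
state a 10,000-individual population visits with probability ~1e-11). The
monotonicity statements for the non-baseline reliabilities are therefore
made over levels `0..T-2`; at the baseline `q = 0.55` they hold over the
full curve.

**Phase diagrams.** `phase_diagram()` tabulates, for every specialization
state `(n0, n1)`, how many individuals passed through it and the
conditional frequency with which the next increment was y0 — the arrows of
a phenotypic phase portrait. The counts obey exact flow conservation
(visits = y0 inflow from the left + y1 inflow from below, with all `N`
individuals at the origin), which the tests assert as a bookkeeping
identity.

**Distribution summaries.** `distribution_summary()` reports histograms
and moments of `n0` at chosen timesteps (5, 10, 20 by default), plus
Sarle's bimodality coefficient

$$b = \frac{g_1^2 + 1}{g_2 + \dfrac{3(n-1)^2}{(n-2)(n-3)}},$$

with `g1`, `g2` the moment estimators of skewness and excess kurtosis. A
uniform distribution gives `b = 5/9` in the large-sample limit, a balanced
two-point distribution approaches 1, and zero-variance or `n < 4` samples
are flagged `NA`. The coefficient was chosen for its closed-form
benchmarks; no dip tests or mixture fits are attempted. Histograms are
reported in `n0`; since `n1 = t - n0`, the difference `n0 - n1` is an
affine transform with identical shape statistics, and its mean is reported
alongside.

**Reliability sweeps.** `reliability_sweep()` crosses the three landscapes
with a grid of cue reliabilities (default `0.5` to `1` in steps of 0.05),
reporting per cell the root value, terminal SD, bimodality and threshold
trend sign, each cell seeded reproducibly from the master seed. Two
degenerate corners are informative: at `q = 1` every individual specializes
fully and correctly (SD 0, root value 1), and at `q = 0.5` the concave
optimum returns every individual to the generalist midpoint — terminal
`n0 = T/2` exactly, zero variance, bimodality undefined — while the convex
optimum sends each individual to a random extreme (a conservative versus
diversified bet-hedging contrast, and the reason the convex-concave SD gap
is maximal at `q = 0.5`).

## Numerical choices

- Posteriors use the odds form above, arranged so that `w = 1` (`q = 0.5`
  or balanced cues) returns the prior bit-exactly; `q = 1` yields exact
  0/1 beliefs through the limits of `r^{2x-t}`.
- Tie tolerance on the value margin is `1e-12` (the margin scale is the
  unit-normalized fitness). Under linear fitness at `q = 0.5` all true
  margins are exactly representable zeros or fall below this comfortably;
  the smallest genuine margin at the baseline `q = 0.55` is ~5e-3.
- Folding `sequential_update()` over a sequence agrees with the count
  closed form to better than 1e-12 whenever the running belief stays
  within `[1e-3, 1 - 1e-3]` (measured worst error 2e-14; 1e-15 at
  `q = 0.55` over the full horizon). A belief within ~1e-13 of certainty
  is absorbing in double precision — `p0` rounds to 1 and no cue can move
  it — so step-by-step folding through near-certain beliefs loses
  precision irrecoverably. This is a property of carrying probabilities as
  doubles, not of the solver, which never folds: it always evaluates the
  closed form at integer counts.
- The expectimax oracle is capped at `T <= 12` (tree size `4^T`),
  exhaustive policy search at `T <= 3` (`2^{20}` policies); both refuse
  larger horizons rather than approximate.

## Problem sizes and study conditions

The defaults mirror the study conditions the analyses are anchored to:
horizon `T = 20`, cue reliability `q = 0.55`, flat prior, populations of
`N = 200` for trajectory illustrations and `N = 10,000` for threshold
estimation and distribution summaries, environment E0. The oracle
cross-checks run every shape at `q` in `{0.55, 0.7, 0.9}` and `T` in
`{2, 3, 4}`. Unit tests that only probe bookkeeping identities use smaller
populations (a few hundred to a few thousand) since the identities are
exact at any `N`.

## What the simulations do and do not show

The simulator generates data exactly from the model's own assumptions:
two discrete environments, conditionally i.i.d. binary cues of constant
reliability, irreversible unit increments, fitness at the end of
development only. Passing tests therefore demonstrate internal consistency
of solver, oracles and analyses, and reproduce the qualitative
population-level signatures (threshold slopes; narrow unimodal versus
bimodal versus skewed terminal distributions). They say nothing about real
developmental data, where environments are graded and changeable, cue
reliabilities drift, increments vary in size or reverse, and fitness
accrues along the way — all deliberately outside this model family, as is
any evolutionary dynamics of the developmental program itself (optima are
computed directly, not evolved).

## Known limitations

- The threshold curve is undefined at levels where y0 is never optimal
  (reported `NA`), and its simulation estimator is a minimum statistic:
  slow-converging at rarely visited levels and one posterior-grid step
  conservative at tied states.
- Sarle's `b` is a screen, not a test: heavy-tailed unimodal distributions
  can exceed 5/9.
- The per-individual substream scheme draws `2T` uniforms per individual
  regardless of path, which is wasteful for very large `N` but guarantees
  prefix stability.
- `exhaustive_policy_search()` at `T = 3` takes a couple of seconds and
  ~8 MB per candidate-policy vector; it exists for validation, not use.
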