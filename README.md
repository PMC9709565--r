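# devfeedbacks

Behavioural individuality often emerges during development through feedback
loops between an animal's behaviour and its state — experience, skill,
information, rank. `devfeedbacks` implements a model in which such
feedbacks are not assumed but *emerge* from adaptive development under
uncertainty, and shows that their sign is set by the curvature of the
fitness landscape. It is written for behavioural ecologists and
developmental modellers who want exact optimal policies, reproducible
population simulations, and the analyses that make the feedback visible.

## The model

An individual lives in one of two environments, E0 or E1, never observed
directly. Over `T = 20` timesteps it receives an imperfect binary cue
(reliability `q`, baseline 0.55), updates its posterior belief
`p0 = P(E0 | cues)` by Bayes' rule, and commits an irreversible unit
increment toward one of two phenotypic specializations, y0 or y1. Only
increments matching the true environment count: terminal fitness is

    f(k) = (k/T)^alpha,   k = matching increments,

with `alpha < 1` (concave, decelerating returns), `alpha = 1` (linear) or
`alpha > 1` (convex, accelerating returns). The exact optimal policy is
computed by finite-horizon stochastic dynamic programming on the integer
state grid (epoch, increments toward y0, c0-cue count), then populations
are simulated forward under it.

The headline result: concave landscapes produce a *negative*
behaviour-state feedback (the posterior threshold for specializing further
rises with accrued specialization), yielding tight unimodal phenotype
distributions; convex landscapes produce a *positive* feedback (the
threshold falls), splitting the population into a bimodal mix of opposite
specialists despite similar beliefs; linear landscapes sever the feedback
entirely (flat threshold at `p0 = 0.5`).

## Worked example

```r
library(devfeedbacks)

cfg <- model_config(fitness = fitness_spec("convex"), N = 10000, seed = 42)
sol <- solve_policy(cfg)
sol
#> optimal developmental policy: T = 20, q = 0.55, convex fitness (alpha = 2)
#>   states: 3080   root value: 0.557645   ties: 0

pop <- simulate_population(cfg, sol)
pop
#> simulated population: N = 10000 in E0, T = 20, q = 0.55, convex fitness
#>   terminal n0: mean 11.69, sd 9.24, range 0..20

head(threshold_curve_from_policy(sol), 4)
#>   n0  tau source
#> 1  0 0.55 policy
#> 2  1 0.50 policy
#> 3  2 0.50 policy
#> 4  3 0.50 policy

distribution_summary(pop, c(5, 10, 20))
#> phenotype distribution summary
#>  timestep     n mean_n0 mean_diff       sd   skewness exkurtosis bimodality
#>         5 10000  2.8209    0.6418 2.185841 -0.2637811  -1.674938  0.8066445
#>        10 10000  5.7579    1.5158 4.464088 -0.3215159  -1.747890  0.8805772
#>        20 10000 11.6884    3.3768 9.241420 -0.3605667  -1.804956  0.9448671
```

Reading the output: the root value 0.557645 is the expected terminal
fitness of an optimal developer before its first cue. The threshold curve
starts at 0.55 and falls — after even one y0 increment, a posterior of 0.5
suffices to keep specializing, the signature of a positive feedback. The
bimodality coefficient climbs to 0.94 by the end of development, far above
the uniform benchmark 5/9 ≈ 0.56: the population has split into opposite
specialists (terminal SD 9.24 on a 0–20 scale). Rerunning with
`fitness_spec("concave")` gives a rising threshold and a terminal
bimodality near 0.53 with SD 4.9 — one homogeneous population of
generalists.

Other entry points: `phase_diagram()` (developmental channeling through
`(n0, n1)` space), `empirical_mean_path()`, `reliability_sweep()` (shapes ×
cue reliabilities), `expectimax_oracle()` / `exhaustive_policy_search()`
(brute-force validation), and `run_pipeline()` / `run_figures()` for
checksummed CSV/JSON output. A command-line wrapper is installed at
`system.file("cli", "devfeedbacks.R", package = "devfeedbacks")`:

```sh
Rscript inst/cli/devfeedbacks.R solve --shape convex --out-dir out/
Rscript inst/cli/devfeedbacks.R figures --seed 1 --out-dir out/figures
```

## Package layout

- `R/` — configuration, belief arithmetic, fitness landscapes, DP solver,
  oracles, simulator, analyses, IO, CLI
- `tests/testthat/` — unit, property and end-to-end suites
- `vignettes/developmental-feedbacks.Rmd` — full methods description
- `inst/extdata/example-config.yaml` — sample configuration file
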