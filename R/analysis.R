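# Derived analyses: decision-threshold curves, phenotypic phase diagrams,
# phenotype-distribution summaries and cue-reliability sweeps. These are the
# quantities that make the sign of the behaviour-state feedback visible:
# a threshold that rises with accrued specialization is a negative feedback,
# a falling one a positive feedback, a flat one no feedback at all.

#' Decision-threshold curve from the exact policy
#'
#' For each accrued specialization level `n0`, the minimum posterior belief
#' in E0 at which a further y0 increment is optimal — i.e. at which y0 enters
#' the optimal action set, counting exact ties, where the policy takes y0
#' with probability one half — taken over all decision epochs `t` and cue
#' counts `x` with that `n0`. Deterministic and exact, and the large-N limit
#' of [threshold_curve_from_simulation()]: under a linear landscape the
#' curve sits flat at the 0.5 boundary. Levels at which y0 is never optimal
#' are reported as `NA`.
#'
#' @param solution A [solve_policy()] result.
#' @return A data frame with columns `n0` (0..T-1), `tau`, `source`
#'   (`"policy"`).
#' @seealso [threshold_by_epoch()] for the un-aggregated per-epoch boundary,
#'   [threshold_curve_from_simulation()] for the Monte-Carlo estimator.
#' @export
threshold_curve_from_policy <- function(solution) {
  stopifnot(inherits(solution, "dp_solution"))
  Tb <- solution$config$T
  tau <- rep(NA_real_, Tb)
  for (t in 1:Tb) {
    post <- solution$posterior[[t]]                  # over x = 0..t
    act <- solution$action[[t]]                      # n0 rows, x cols
    for (n0 in 0:(t - 1)) {
      p <- post[act[n0 + 1L, ] >= 0L]      # y0 strictly optimal or tied
      if (length(p) > 0L) {
        tau[n0 + 1L] <- min(tau[n0 + 1L], min(p), na.rm = TRUE)
      }
    }
  }
  data.frame(n0 = 0:(Tb - 1), tau = tau, source = "policy")
}

#' Per-epoch decision boundary
#'
#' The un-aggregated threshold: for every `(t, n0)` pair, the minimum
#' posterior at which y0 is optimal (counting ties) at epoch `t`. The
#' aggregated threshold curve takes the minimum of this over epochs; the
#' epoch slices are exposed for diagnostics.
#'
#' @param solution A [solve_policy()] result.
#' @return A data frame with columns `t`, `n0`, `tau` (`NA` where y0 is never
#'   optimal at that epoch).
#' @export
threshold_by_epoch <- function(solution) {
  stopifnot(inherits(solution, "dp_solution"))
  Tb <- solution$config$T
  do.call(rbind, lapply(1:Tb, function(t) {
    post <- solution$posterior[[t]]
    act <- solution$action[[t]]
    tau <- vapply(0:(t - 1), function(n0) {
      p <- post[act[n0 + 1L, ] >= 0L]
      if (length(p) > 0L) min(p) else NA_real_
    }, numeric(1))
    data.frame(t = t, n0 = 0:(t - 1), tau = tau)
  }))
}

#' Decision-threshold curve estimated from a simulated population
#'
#' Groups every decision event of the population by the deciding
#' individual's current `n0` and reports the minimum posterior among events
#' where y0 was chosen. Converges to the policy-exact curve restricted to
#' the states the population actually visits; unvisited or never-chosen
#' levels are `NA` (not an error).
#'
#' @param result A [simulate_population()] result.
#' @return A data frame with columns `n0` (0..T-1), `tau`, `source`
#'   (`"simulation"`).
#' @export
threshold_curve_from_simulation <- function(result) {
  stopifnot(inherits(result, "population_result"))
  Tb <- result$config$T
  n0_before <- result$n0_path[, 1:Tb, drop = FALSE]
  chose_y0 <- result$actions == 1L
  tau <- rep(NA_real_, Tb)
  if (any(chose_y0)) {
    mins <- tapply(result$posteriors[chose_y0], n0_before[chose_y0], min)
    tau[as.integer(names(mins)) + 1L] <- as.numeric(mins)
  }
  data.frame(n0 = 0:(Tb - 1), tau = tau, source = "simulation")
}

#' Phenotypic phase diagram
#'
#' Empirical flow of the population through the specialization grid: for each
#' state `(n0, n1)` with `n0 + n1 < T`, the number of individuals that passed
#' through it and, conditional on being there, the frequency with which the
#' next increment was y0 (the quantity the phase-space arrows encode).
#' States never visited carry `NA` frequencies. Counts obey exact flow
#' conservation: the visits to a state equal the y0 inflow from
#' `(n0 - 1, n1)` plus the y1 inflow from `(n0, n1 - 1)`, with all `N`
#' individuals at the origin.
#'
#' @param result A [simulate_population()] result.
#' @return A data frame with columns `n0`, `n1`, `count`, `n_y0` (visits that
#'   continued toward y0) and `p_y0 = n_y0 / count`.
#' @export
phase_diagram <- function(result) {
  stopifnot(inherits(result, "population_result"))
  Tb <- result$config$T
  rows <- lapply(1:Tb, function(t) {
    n0 <- result$n0_path[, t]                        # state before decision t
    a <- result$actions[, t]
    cnt <- tabulate(n0 + 1L, nbins = t)              # n0 in 0..t-1
    y0 <- vapply(0:(t - 1), function(k) sum(a[n0 == k]), numeric(1))
    data.frame(n0 = 0:(t - 1), n1 = (t - 1):0, count = cnt, n_y0 = y0)
  })
  df <- do.call(rbind, rows)
  df$p_y0 <- ifelse(df$count > 0, df$n_y0 / df$count, NA_real_)
  df
}

#' Sarle's bimodality coefficient
#'
#' Moment-based bimodality screen
#' \deqn{b = \frac{g_1^2 + 1}{g_2 + \frac{3 (n-1)^2}{(n-2)(n-3)}}}
#' with `g1` the sample skewness and `g2` the sample excess kurtosis
#' (moment estimators). A large sample from a uniform distribution gives
#' `b = 5/9`; values above that lean bimodal (a balanced two-point
#' distribution approaches 1), values below lean unimodal-peaked. Undefined
#' (`NA`) for `n < 4` or zero variance.
#'
#' @param x Numeric sample.
#' @return The coefficient in `(0, 1]`, or `NA`.
#' @export
bimodality_coefficient <- function(x) {
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(NA_real_)
  g1 <- e1071::skewness(x, type = 1)
  g2 <- e1071::kurtosis(x, type = 1)
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Phenotype-distribution summaries at chosen timesteps
#'
#' Summarizes the spread of individual variation in the population at the
#' requested timesteps (classically 5, 10 and 20: early, midway and the end
#' of development): a histogram of `n0` and moment summaries, including
#' Sarle's bimodality coefficient. Since `n1 = t - n0`, the difference
#' `n0 - n1 = 2 n0 - t` is an affine transform of `n0`, so its mean is
#' reported alongside while the shape statistics of the two variables
#' coincide.
#'
#' @param result A [simulate_population()] result.
#' @param timesteps Integer timesteps in `1..T` at which to summarize.
#' @return An object of class `distribution_summary`: `moments`, a data frame
#'   with one row per timestep (`timestep`, `n`, `mean_n0`, `mean_diff`,
#'   `sd`, `skewness`, `exkurtosis`, `bimodality`), and `histogram`, a long
#'   data frame (`timestep`, `n0`, `count`) whose counts sum to `N` within
#'   each timestep.
#' @export
distribution_summary <- function(result, timesteps = c(5, 10, 20)) {
  stopifnot(inherits(result, "population_result"))
  Tb <- result$config$T
  timesteps <- sort(unique(as.integer(timesteps)))
  if (any(timesteps < 1L | timesteps > Tb)) {
    stop(sprintf("`timesteps` must lie in 1..%d", Tb))
  }
  moments <- do.call(rbind, lapply(timesteps, function(ts) {
    n0 <- result$n0_path[, ts + 1L]
    zero_var <- stats::var(n0) == 0
    data.frame(
      timestep = ts,
      n = length(n0),
      mean_n0 = mean(n0),
      mean_diff = mean(2 * n0 - ts),
      sd = stats::sd(n0),
      skewness = if (zero_var) NA_real_ else e1071::skewness(n0, type = 1),
      exkurtosis = if (zero_var) NA_real_ else e1071::kurtosis(n0, type = 1),
      bimodality = bimodality_coefficient(n0)
    )
  }))
  histogram <- do.call(rbind, lapply(timesteps, function(ts) {
    n0 <- result$n0_path[, ts + 1L]
    data.frame(timestep = ts, n0 = 0:ts,
               count = tabulate(n0 + 1L, nbins = ts + 1L))
  }))
  structure(list(moments = moments, histogram = histogram),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat("phenotype distribution summary\n")
  print(x$moments, row.names = FALSE)
  invisible(x)
}

# trend of a threshold curve over defined entries:
# +1 non-decreasing, -1 non-increasing, 0 constant, NA mixed
threshold_trend <- function(tau, tol = 1e-9) {
  d <- diff(tau[!is.na(tau)])
  if (length(d) == 0L) return(NA_real_)
  if (all(abs(d) <= tol)) 0
  else if (all(d >= -tol)) 1
  else if (all(d <= tol)) -1
  else NA_real_
}

#' Sweep cue reliability and fitness shape
#'
#' Solves and simulates the model over a grid of cue reliabilities for each
#' fitness landscape, summarizing each cell by the root value of the optimal
#' policy, the terminal-phenotype standard deviation and bimodality
#' coefficient, and the monotonicity sign of the policy-exact threshold
#' curve (+1 rising = negative feedback, -1 falling = positive feedback,
#' 0 flat = no feedback). Every cell's simulation seed is derived
#' reproducibly from the base configuration's master seed.
#'
#' @param config Base [model_config()]; its `T`, `prior_p0`, `N`, `true_env`
#'   and `seed` are shared across cells.
#' @param q_grid Cue reliabilities to sweep.
#' @param shapes List of [fitness_spec()]s (default: the three canonical
#'   landscapes).
#' @return A data frame with one row per `(shape, q)` cell: `q`, `shape`,
#'   `alpha`, `root_value`, `sd`, `b`, `tau_trend`.
#' @export
reliability_sweep <- function(config,
                              q_grid = seq(0.5, 1, by = 0.05),
                              shapes = list(fitness_spec("concave"),
                                            fitness_spec("linear"),
                                            fitness_spec("convex"))) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  cell_seeds <- sample.int(.Machine$integer.max,
                           length(shapes) * length(q_grid))
  rows <- list()
  k <- 0L
  for (spec in shapes) {
    for (q in q_grid) {
      k <- k + 1L
      cfg <- model_config(T = config$T, q = q, prior_p0 = config$prior_p0,
                          fitness = spec, N = config$N,
                          true_env = config$true_env, seed = cell_seeds[k])
      sol <- solve_policy(cfg)
      pop <- simulate_population(cfg, sol)
      thr <- threshold_curve_from_policy(sol)
      rows[[k]] <- data.frame(
        q = q, shape = spec$shape, alpha = spec$alpha,
        root_value = sol$root_value,
        sd = stats::sd(pop$terminal_n0),
        b = bimodality_coefficient(pop$terminal_n0),
        tau_trend = threshold_trend(thr$tau)
      )
    }
  }
  do.call(rbind, rows)
}
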