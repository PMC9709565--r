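test_that("threshold curves carry the feedback sign of each landscape", {
  taus <- lapply(the_shapes, function(shape) {
    threshold_curve_from_policy(solve_policy(base_config(shape)))$tau
  })
  names(taus) <- the_shapes
  expect_true(all(!is.na(unlist(taus))))
  # concave: rising threshold = negative feedback
  expect_true(all(diff(taus$concave) >= -1e-12))
  expect_gt(max(taus$concave) - min(taus$concave), 0.1)
  # linear: flat at the 0.5 boundary = no feedback
  expect_true(all(abs(taus$linear - 0.5) <= 1e-9))
  # convex: falling threshold = positive feedback
  expect_true(all(diff(taus$convex) <= 1e-12))
  expect_gt(max(taus$convex) - min(taus$convex), 0.1)
})

test_that("the aggregated threshold is the minimum of the per-epoch boundaries", {
  sol <- solve_policy(base_config("convex"))
  agg <- threshold_curve_from_policy(sol)
  slices <- threshold_by_epoch(sol)
  by_min <- tapply(slices$tau, slices$n0, min, na.rm = TRUE)
  expect_equal(as.numeric(by_min), agg$tau)
})

test_that("simulation-estimated thresholds track the policy on visited states", {
  # deterministic single path under perfect cues
  cfg <- model_config(q = 1, N = 20, fitness = fitness_spec("convex"), seed = 2)
  sol <- solve_policy(cfg)
  thr <- threshold_curve_from_simulation(simulate_population(cfg, sol))
  expect_equal(thr$tau, rep(1, 20))
  # within one reachable-posterior grid step of the exact curve on visited states
  for (shape in the_shapes) {
    cfg <- base_config(shape, N = 10000, seed = 13)
    sol <- solve_policy(cfg)
    pop <- simulate_population(cfg, sol)
    ts <- threshold_curve_from_simulation(pop)$tau
    tv <- policy_tau_on_visited(sol, pop)
    for (i in seq_along(ts)) {
      if (!is.na(ts[i]) && !is.na(tv[i])) {
        expect_lte(posterior_grid_gap(sol, ts[i], tv[i]), 1)
      }
    }
  }
})

test_that("a population that never chose y0 yields an all-undefined threshold curve", {
  cfg <- model_config(q = 1, N = 1, fitness = fitness_spec("convex"),
                      true_env = "E1", seed = 4)
  pop <- simulate_population(cfg, solve_policy(cfg))
  expect_true(all(pop$actions == 0L))  # only y1 under perfect E1 cues
  expect_true(all(is.na(threshold_curve_from_simulation(pop)$tau)))
})

test_that("phase diagrams conserve population flow exactly", {
  for (shape in c("concave", "convex")) {
    cfg <- base_config(shape, N = 2000, seed = 7)
    pop <- simulate_population(cfg, solve_policy(cfg))
    ph <- phase_diagram(pop)
    expect_flow_conserved(ph, 2000)
    expect_true(all(ph$p_y0 >= 0 & ph$p_y0 <= 1, na.rm = TRUE))
  }
  # perfect cues: all mass on the n1 = 0 spine, every arrow pointing to y0
  cfg <- model_config(q = 1, N = 100, fitness = fitness_spec("concave"),
                      seed = 2)
  ph <- phase_diagram(simulate_population(cfg, solve_policy(cfg)))
  expect_true(all(ph$count[ph$n1 > 0] == 0))
  expect_true(all(ph$p_y0[ph$count > 0] == 1))
})

test_that("positive feedback keeps early leaders specializing", {
  cfg <- base_config("convex", N = 10000, seed = 7)
  pop <- simulate_population(cfg, solve_policy(cfg))
  ph <- phase_diagram(pop)
  lead <- ph$count > 0 & ph$n0 >= ph$n1 + 4
  expect_gt(mean(ph$p_y0[lead]), 0.9)
})

test_that("bimodality coefficient matches its closed-form benchmarks", {
  expect_true(is.na(bimodality_coefficient(rep(3, 100))))   # zero variance
  expect_true(is.na(bimodality_coefficient(c(1, 2, 3))))    # n < 4
  set.seed(20260924)
  expect_equal(bimodality_coefficient(runif(100000)), 5 / 9, tolerance = 0.02)
  # balanced two-point distribution: minimal kurtosis, b -> 1
  expect_gt(bimodality_coefficient(rep(c(0, 20), 2000)), 0.99)
})

test_that("distribution summaries flag degenerate spreads and sum to N", {
  cfg <- model_config(q = 1, N = 60, fitness = fitness_spec("linear"), seed = 8)
  pop <- simulate_population(cfg, solve_policy(cfg))
  ds <- distribution_summary(pop, c(5, 10, 20))
  expect_true(all(is.na(ds$moments$bimodality)))  # everyone at n0 = t
  expect_true(all(ds$moments$sd == 0))
  expect_true(all(tapply(ds$histogram$count, ds$histogram$timestep, sum) == 60))
  expect_error(distribution_summary(pop, 25), "1\\.\\.20")
  # n0 - n1 = 2 n0 - t bookkeeping
  expect_equal(ds$moments$mean_diff, 2 * ds$moments$mean_n0 - c(5, 10, 20))
})

test_that("landscape curvature orders the spread and modality of phenotypes", {
  mom <- lapply(the_shapes, function(shape) {
    cfg <- base_config(shape, N = 3000, seed = 77)
    ds <- distribution_summary(simulate_population(cfg, solve_policy(cfg)), 20)
    ds$moments
  })
  names(mom) <- the_shapes
  expect_gt(mom$convex$bimodality, 5 / 9)
  expect_lt(mom$concave$bimodality, 5 / 9)
  expect_gt(mom$convex$sd, mom$concave$sd)
  expect_gt(abs(mom$linear$skewness), 0.1)
})

test_that("reliability sweeps are deterministic and degenerate correctly at q = 1", {
  cfg <- base_config("concave", N = 400, seed = 31)
  grid <- c(0.5, 0.75, 1)
  sw <- reliability_sweep(cfg, q_grid = grid)
  expect_identical(nrow(sw), 9L)
  expect_identical(sw, reliability_sweep(cfg, q_grid = grid))
  expect_true(all(sw$sd[sw$q == 1] == 0))
  expect_true(all(sw$root_value[sw$q == 1] == 1))
  # feedback sign is the shape's own, across reliabilities (q > 0.5)
  mid <- sw$q == 0.75
  expect_identical(sw$tau_trend[mid & sw$shape == "concave"], 1)
  expect_identical(sw$tau_trend[mid & sw$shape == "linear"], 0)
  expect_identical(sw$tau_trend[mid & sw$shape == "convex"], -1)
})

test_that("maximal uncertainty produces the starkest individuality contrast", {
  cfg <- base_config("concave", N = 4000, seed = 41)
  sw <- reliability_sweep(cfg, q_grid = c(0.5, 0.55, 0.75, 0.95))
  sd_gap <- sw$sd[sw$shape == "convex"] - sw$sd[sw$shape == "concave"]
  expect_equal(which.max(sd_gap), 1L)  # q = 0.5 first in the grid
  b_convex <- sw$b[sw$shape == "convex"]
  expect_equal(which.max(b_convex), 1L)
  # conservative bet-hedging: at q = 0.5 the concave population collapses
  # onto the generalist midpoint (zero variance, bimodality undefined)
  expect_identical(sw$sd[sw$shape == "concave" & sw$q == 0.5], 0)
  expect_true(is.na(sw$b[sw$shape == "concave" & sw$q == 0.5]))
})
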