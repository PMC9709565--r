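test_that("the one-step problem is solved by following the single cue", {
  for (shape in the_shapes) {
    sol <- solve_policy(model_config(T = 1, fitness = fitness_spec(shape)))
    # first cue is c0/c1 with probability one half; follow it at reliability q
    expect_equal(sol$root_value, 0.55, tolerance = 1e-14)
    expect_identical(sol$action[[1]][1, 2], 1L)   # x = 1 -> specialize to y0
    expect_identical(sol$action[[1]][1, 1], -1L)  # x = 0 -> specialize to y1
  }
})

test_that("uninformative cues give the closed-form root values", {
  rv <- function(shape) {
    solve_policy(model_config(q = 0.5, fitness = fitness_spec(shape)))$root_value
  }
  # belief pinned at 1/2: expected fitness of ending at n0 is
  # (f(n0) + f(T - n0)) / 2, maximized at the extremes (convex), flat
  # (linear) or at T/2 (concave, value (1/2)^alpha)
  expect_equal(rv("convex"), 0.5, tolerance = 1e-12)
  expect_equal(rv("linear"), 0.5, tolerance = 1e-12)
  expect_equal(rv("concave"), 0.7071067811865476, tolerance = 1e-12)
})

test_that("values are bounded and symmetric, actions antisymmetric, under a flat prior", {
  for (shape in the_shapes) {
    sol <- solve_policy(model_config(fitness = fitness_spec(shape)))
    expect_true(sol$root_value >= 0 && sol$root_value <= 1)
    for (t in 1:20) {
      V <- sol$V[[t]]
      A <- sol$action[[t]]
      expect_true(all(V >= 0 & V <= 1))
      # swapping (E0, c0, y0) <-> (E1, c1, y1) maps (n0, x) to (t-1-n0, t-x)
      expect_equal(V, V[t:1, (t + 1):1, drop = FALSE], tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_identical(A, -A[t:1, (t + 1):1, drop = FALSE])
    }
  }
})

test_that("more reliable cues never reduce the optimal value", {
  for (shape in the_shapes) {
    rv <- vapply(seq(0.5, 1, 0.05), function(q) {
      solve_policy(model_config(q = q, fitness = fitness_spec(shape)))$root_value
    }, numeric(1))
    expect_true(all(diff(rv) >= -1e-12))
  }
})

test_that("action lookup is deterministic off ties and a fair coin on ties", {
  sol <- solve_policy(base_config("convex"))
  pt <- policy_table(sol)
  y0_row <- pt[pt$action == "y0", ][1, ]
  y1_row <- pt[pt$action == "y1", ][1, ]
  set.seed(1)
  expect_true(all(replicate(20, optimal_action(sol, y0_row$t, y0_row$n0,
                                               y0_row$x)) == "y0"))
  expect_true(all(replicate(20, optimal_action(sol, y1_row$t, y1_row$n0,
                                               y1_row$x)) == "y1"))
  # with q = 0.5 and linear fitness every state is tied
  sol5 <- solve_policy(model_config(q = 0.5, fitness = fitness_spec("linear")))
  set.seed(20260922)
  draws <- replicate(10000, optimal_action(sol5, 1, 0, 0))
  expect_gt(mean(draws == "y0"), 0.48)
  expect_lt(mean(draws == "y0"), 0.52)
  expect_error(optimal_action(sol, 21, 0, 0), "t")
  expect_error(optimal_action(sol, 3, 3, 1), "n0")
  expect_error(optimal_action(sol, 3, 1, 4), "x")
})

test_that("the myopic MAP policy is exactly optimal under linear fitness", {
  cfg <- model_config(fitness = fitness_spec("linear"))
  sol <- solve_policy(cfg)
  gr <- greedy_map_policy(cfg)
  for (t in 1:20) {
    expect_identical(sol$action[[t]], gr$action[[t]])
  }
  # spot values: one net c0 cue -> specialize toward E0; balanced -> tie
  expect_identical(gr$action[[1]][1, 2], 1L)
  expect_identical(gr$action[[2]][1, 2], 0L)
  expect_error(greedy_map_policy(base_config("convex")), "linear")
})

test_that("policy and value tables enumerate the state space in canonical order", {
  sol <- solve_policy(base_config("concave"))
  pt <- policy_table(sol)
  vt <- value_table(sol)
  expect_identical(nrow(pt), 3080L)  # sum over t of t * (t + 1)
  expect_identical(nrow(vt), 3080L)
  expect_identical(names(pt), c("t", "n0", "x", "posterior", "delta", "action"))
  # deterministic (t, n0, x) ordering
  key <- order(pt$t, pt$n0, pt$x)
  expect_identical(key, seq_len(nrow(pt)))
  expect_true(all(pt$n0 <= pt$t - 1) && all(pt$x <= pt$t))
  pt1 <- policy_table(solve_policy(model_config(T = 1)))
  expect_identical(nrow(pt1), 2L)
  # posterior column is the exact count-based posterior
  expect_equal(pt$posterior,
               posterior_from_counts(pt$t, pt$x, 0.55, 0.5), tolerance = 1e-15)
})
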