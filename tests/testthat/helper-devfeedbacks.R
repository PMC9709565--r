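# shared fixtures and independent oracles for the test suite

the_shapes <- c("concave", "linear", "convex")

base_config <- function(shape = "concave", ...) {
  model_config(fitness = fitness_spec(shape), ...)
}

# independent Bayes oracle: raw likelihood product over an explicit cue
# sequence (1 = c0), no odds-form shortcut
bayes_product_posterior <- function(cues, q, prior_p0) {
  l0 <- prod(ifelse(cues == 1, q, 1 - q))
  l1 <- prod(ifelse(cues == 1, 1 - q, q))
  prior_p0 * l0 / (prior_p0 * l0 + (1 - prior_p0) * l1)
}

# policy-exact threshold restricted to the (t, n0, x) states a population
# visited: the limit the simulation estimator converges to
policy_tau_on_visited <- function(solution, pop) {
  Tb <- solution$config$T
  tau <- rep(NA_real_, Tb)
  for (t in 1:Tb) {
    x_t <- rowSums(pop$cues[, 1:t, drop = FALSE])
    st <- unique(cbind(pop$n0_path[, t], x_t))
    for (r in seq_len(nrow(st))) {
      n0 <- st[r, 1]
      x <- st[r, 2]
      if (solution$action[[t]][n0 + 1, x + 1] >= 0L) {
        tau[n0 + 1] <- min(tau[n0 + 1], solution$posterior[[t]][x + 1],
                           na.rm = TRUE)
      }
    }
  }
  tau
}

# index distance of two posteriors on the reachable-posterior grid
posterior_grid_gap <- function(solution, a, b) {
  g <- sort(unique(unlist(solution$posterior)))
  abs(which.min(abs(g - a)) - which.min(abs(g - b)))
}

# exact flow-conservation check on a phase diagram: visits to a cell equal
# the y0 inflow from the left neighbour plus the y1 inflow from below
expect_flow_conserved <- function(ph, N) {
  key <- function(n0, n1) paste(n0, n1)
  cnt <- stats::setNames(ph$count, key(ph$n0, ph$n1))
  y0 <- stats::setNames(ph$n_y0, key(ph$n0, ph$n1))
  for (i in seq_len(nrow(ph))) {
    n0 <- ph$n0[i]
    n1 <- ph$n1[i]
    expected <- if (n0 + n1 == 0) {
      N
    } else {
      left <- key(n0 - 1, n1)
      below <- key(n0, n1 - 1)
      (if (left %in% names(y0)) y0[[left]] else 0) +
        (if (below %in% names(cnt)) cnt[[below]] - y0[[below]] else 0)
    }
    expect_identical(as.integer(ph$count[i]), as.integer(expected))
  }
  invisible(NULL)
}
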