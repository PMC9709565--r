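# Deterministic serialization of solved policies, simulations and derived
# analyses. CSV (header row, fixed column order, fixed row order) is the
# interchange format for tables, JSON for scalar summaries and manifests.

write_csv_det <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

trajectories_frame <- function(pop) {
  Tb <- pop$config$T
  N <- pop$config$N
  data.frame(
    individual = rep(seq_len(N), each = Tb),
    t = rep(1:Tb, times = N),
    cue = c("c1", "c0")[as.integer(t(pop$cues)) + 1L],
    posterior = as.numeric(t(pop$posteriors)),
    action = c("y1", "y0")[as.integer(t(pop$actions)) + 1L],
    n0 = as.integer(t(pop$n0_path[, -1L, drop = FALSE])),
    n1 = rep(1:Tb, times = N) - as.integer(t(pop$n0_path[, -1L, drop = FALSE]))
  )
}

config_echo <- function(config) {
  list(T = config$T, q = config$q, prior_p0 = config$prior_p0,
       fitness = list(shape = config$fitness$shape,
                      alpha = config$fitness$alpha),
       N = config$N, true_env = config$true_env, seed = config$seed)
}

write_manifest <- function(out_dir, config, files, stage_seeds = NULL) {
  files <- files[order(basename(files))]
  sums <- tools::md5sum(files)
  manifest <- list(
    package = "devfeedbacks",
    version = as.character(utils::packageVersion("devfeedbacks")),
    config = config_echo(config),
    master_seed = config$seed,
    stage_seeds = stage_seeds,
    checksums = as.list(stats::setNames(as.character(sums), basename(files)))
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Solve a model and write the policy and value tables
#'
#' Runs [solve_policy()] and writes `policy.csv` and `values.csv` (one row
#' per state, ordered by `t`, `n0`, `x`) plus a `manifest.json` echoing the
#' configuration and recording MD5 checksums of the outputs. The solver is
#' deterministic, so these files do not depend on the seed.
#'
#' @param config A [model_config()].
#' @param out_dir Output directory, created if needed.
#' @return (Invisibly) the `dp_solution`.
#' @export
run_solve <- function(config, out_dir) {
  stopifnot(inherits(config, "model_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sol <- solve_policy(config)
  files <- c(
    write_csv_det(policy_table(sol), file.path(out_dir, "policy.csv")),
    write_csv_det(value_table(sol), file.path(out_dir, "values.csv"))
  )
  write_manifest(out_dir, config, files)
  invisible(sol)
}

#' Run the full pipeline for one model configuration
#'
#' Solve, simulate, and derive all analyses for a single `(shape, q)`
#' setting, writing `policy.csv`, `values.csv`, `trajectories.csv`,
#' `thresholds.csv` (policy-exact and simulation-estimated curves stacked),
#' `phase.csv`, `distributions.csv`, a `summary.json` of scalar results and
#' a checksummed `manifest.json`. A single master seed governs every
#' stochastic stage.
#'
#' @param config A [model_config()].
#' @param out_dir Output directory, created if needed.
#' @param timesteps Timesteps summarized by [distribution_summary()]
#'   (defaults to 5, 10 and the horizon, clipped to `1..T`).
#' @return (Invisibly) a list with the solution, population and analyses.
#' @export
run_pipeline <- function(config, out_dir,
                         timesteps = unique(pmin(c(5L, 10L, config$T),
                                                 config$T))) {
  stopifnot(inherits(config, "model_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  sol <- solve_policy(config)
  message(sprintf("solve: T = %d, q = %g, %s (%.2fs)", config$T, config$q,
                  config$fitness$shape, proc.time()[["elapsed"]] - t0))
  pop <- simulate_population(config, sol)
  thr <- rbind(threshold_curve_from_policy(sol),
               threshold_curve_from_simulation(pop))
  phase <- phase_diagram(pop)
  dist <- distribution_summary(pop, timesteps)
  mean_path <- empirical_mean_path(pop)

  files <- c(
    write_csv_det(policy_table(sol), file.path(out_dir, "policy.csv")),
    write_csv_det(value_table(sol), file.path(out_dir, "values.csv")),
    write_csv_det(trajectories_frame(pop),
                  file.path(out_dir, "trajectories.csv")),
    write_csv_det(thr, file.path(out_dir, "thresholds.csv")),
    write_csv_det(phase, file.path(out_dir, "phase.csv")),
    write_csv_det(dist$histogram, file.path(out_dir, "distributions.csv"))
  )
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(root_value = sol$root_value,
         terminal_distribution = as.list(stats::setNames(
           tabulate(pop$terminal_n0 + 1L, nbins = config$T + 1L),
           as.character(0:config$T))),
         mean_path = mean_path,
         moments = dist$moments),
    summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  write_manifest(out_dir, config, c(files, summary_path))
  invisible(list(solution = sol, population = pop, thresholds = thr,
                 phase = phase, distributions = dist, mean_path = mean_path))
}

#' Emit the data behind the headline analyses
#'
#' Runs the three canonical fitness landscapes at the baseline conditions
#' (`T = 20`, `q = 0.55`, flat prior, environment E0) and writes, per shape
#' (subdirectories `concave/`, `convex/`, `linear/`): the full pipeline of a
#' 200-individual population (the trajectory-plot data) and, from a separate
#' 10,000-individual population, `thresholds.csv`, `phase.csv` and
#' `distributions.csv` (the threshold-curve, phase-diagram and histogram
#' data).
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param q Cue reliability (default 0.55).
#' @param T Developmental horizon (default 20).
#' @param N_traj Population size for trajectory outputs (default 200).
#' @param N_threshold Population size for threshold/phase/distribution
#'   outputs (default 10,000).
#' @return (Invisibly) the per-shape result lists.
#' @export
run_figures <- function(out_dir, seed = 1L, q = 0.55, T = 20L,
                        N_traj = 200L, N_threshold = 10000L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max, 6L)
  shapes <- c("concave", "convex", "linear")
  out <- list()
  for (i in seq_along(shapes)) {
    shape <- shapes[i]
    sub <- file.path(out_dir, shape)
    cfg_traj <- model_config(T = T, q = q, fitness = fitness_spec(shape),
                             N = N_traj, true_env = "E0",
                             seed = stage_seeds[2L * i - 1L])
    res <- run_pipeline(cfg_traj, sub)

    cfg_big <- model_config(T = T, q = q, fitness = fitness_spec(shape),
                            N = N_threshold, true_env = "E0",
                            seed = stage_seeds[2L * i])
    pop <- simulate_population(cfg_big, res$solution)
    thr <- rbind(threshold_curve_from_policy(res$solution),
                 threshold_curve_from_simulation(pop))
    files <- c(
      write_csv_det(thr, file.path(sub, "thresholds.csv")),
      write_csv_det(phase_diagram(pop), file.path(sub, "phase.csv")),
      write_csv_det(distribution_summary(pop)$histogram,
                    file.path(sub, "distributions.csv")),
      file.path(sub, c("policy.csv", "values.csv", "trajectories.csv",
                       "summary.json"))
    )
    write_manifest(sub, cfg_big, files,
                   stage_seeds = list(trajectories = cfg_traj$seed,
                                      thresholds = cfg_big$seed))
    out[[shape]] <- res
  }
  invisible(out)
}
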