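#' Fitness landscape specification
#'
#' Describes the map from the number of environment-matching developmental
#' increments accrued by the end of development to terminal fitness. The
#' family is the normalized power curve \eqn{f(k) = (k/T)^\alpha}, which spans
#' the three curvature classes the model distinguishes: concave (decelerating
#' returns to specialization, `0 < alpha < 1`), convex (accelerating returns,
#' `alpha > 1`) and linear (constant returns, `alpha = 1`).
#'
#' @param shape One of `"concave"`, `"convex"`, `"linear"`.
#' @param alpha Curvature exponent. Defaults to 0.5 (concave), 2 (convex) and
#'   1 (linear). `linear` forces `alpha = 1`; `concave` requires
#'   `0 < alpha < 1`; `convex` requires `alpha > 1`.
#' @return An object of class `fitness_spec` with elements `shape` and `alpha`.
#' @examples
#' fitness_spec("concave")
#' fitness_spec("convex", alpha = 3)
#' @export
fitness_spec <- function(shape = c("concave", "convex", "linear"),
                         alpha = NULL) {
  shape <- match.arg(shape)
  if (is.null(alpha)) {
    alpha <- switch(shape, concave = 0.5, convex = 2, linear = 1)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop(config_error("`alpha` must be a single positive finite number"))
  }
  ok <- switch(shape,
    concave = alpha < 1,
    convex  = alpha > 1,
    linear  = alpha == 1
  )
  if (!ok) {
    stop(config_error(sprintf(
      "alpha = %g is incompatible with shape '%s' (concave needs 0 < alpha < 1, convex alpha > 1, linear alpha = 1)",
      alpha, shape
    )))
  }
  structure(list(shape = shape, alpha = alpha), class = "fitness_spec")
}

#' Model configuration
#'
#' Bundles all free parameters of one model instance. Defaults are the
#' baseline study conditions: a 20-step developmental horizon, cue reliability
#' 0.55, a flat prior over the two environments, and populations of 200
#' individuals (use `N = 10000` for threshold estimation).
#'
#' @param T Developmental horizon: number of timesteps (positive integer).
#' @param q Cue reliability, the probability that a cue matches the true
#'   environment; must lie in `[0.5, 1]`. `q = 0.5` is uninformative,
#'   `q = 1` perfect.
#' @param prior_p0 Prior probability of environment E0, in `(0, 1)`.
#' @param fitness A [fitness_spec()].
#' @param N Population size for forward simulation (positive integer).
#' @param true_env The environment the simulated population actually lives in,
#'   `"E0"` or `"E1"`.
#' @param seed Master RNG seed (integer); every stochastic stage derives its
#'   stream from it.
#' @return An object of class `model_config`.
#' @examples
#' model_config(fitness = fitness_spec("convex"))
#' @export
model_config <- function(T = 20L, q = 0.55, prior_p0 = 0.5,
                         fitness = fitness_spec("concave"),
                         N = 200L, true_env = c("E0", "E1"), seed = 1L) {
  true_env <- match.arg(true_env)
  if (!is.numeric(T) || length(T) != 1L || T < 1 || T != round(T)) {
    stop(config_error("`T` must be a positive integer"))
  }
  if (!is.numeric(q) || length(q) != 1L || q < 0.5 || q > 1) {
    stop(config_error("`q` must lie in [0.5, 1]"))
  }
  if (!is.numeric(prior_p0) || length(prior_p0) != 1L ||
      prior_p0 <= 0 || prior_p0 >= 1) {
    stop(config_error("`prior_p0` must lie strictly in (0, 1)"))
  }
  if (!inherits(fitness, "fitness_spec")) {
    stop(config_error("`fitness` must be a fitness_spec object"))
  }
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N)) {
    stop(config_error("`N` must be a positive integer"))
  }
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)) {
    stop(config_error("`seed` must be an integer"))
  }
  structure(
    list(T = as.integer(T), q = as.numeric(q), prior_p0 = as.numeric(prior_p0),
         fitness = fitness, N = as.integer(N), true_env = true_env,
         seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Read a model configuration from a YAML or JSON file
#'
#' Keys match the [model_config()] field names (`T`, `q`, `prior_p0`,
#' `fitness` — itself a mapping with `shape` and optional `alpha` —, `N`,
#' `true_env`, `seed`); every key is optional and falls back to the default.
#' Unknown keys are an error listing the offenders.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `model_config`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) {
    stop(config_error(sprintf("config file '%s' does not exist", path)))
  }
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      yaml = ,
      yml  = yaml::read_yaml(path),
      json = jsonlite::read_json(path, simplifyVector = TRUE),
      stop(config_error(sprintf("unsupported config extension '%s'", ext)))
    ),
    error = function(e) {
      if (inherits(e, "devfeedbacks_config_error")) stop(e)
      stop(config_error(sprintf("failed to parse '%s': %s", path,
                                conditionMessage(e))))
    }
  )
  if (!is.list(raw)) stop(config_error("config file must contain a mapping"))
  # YAML 1.1 reads a bare key `N` as boolean false; map it back to the field
  names(raw)[names(raw) == "FALSE"] <- "N"
  known <- c("T", "q", "prior_p0", "fitness", "N", "true_env", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L) {
    stop(config_error(sprintf("unknown config keys: %s",
                              paste(bad, collapse = ", "))))
  }
  if (!is.null(raw$fitness)) {
    fk <- setdiff(names(raw$fitness), c("shape", "alpha"))
    if (length(fk) > 0L) {
      stop(config_error(sprintf("unknown fitness keys: %s",
                                paste(fk, collapse = ", "))))
    }
    raw$fitness <- do.call(fitness_spec, raw$fitness)
  }
  do.call(model_config, raw)
}

#' @export
print.fitness_spec <- function(x, ...) {
  cat(sprintf("fitness landscape: %s, f(k) = (k/T)^%g\n", x$shape, x$alpha))
  invisible(x)
}

#' @export
print.model_config <- function(x, ...) {
  cat("model configuration\n")
  cat(sprintf("  horizon T      : %d timesteps\n", x$T))
  cat(sprintf("  cue reliability: q = %g\n", x$q))
  cat(sprintf("  prior P(E0)    : %g\n", x$prior_p0))
  cat(sprintf("  fitness        : %s (alpha = %g)\n",
              x$fitness$shape, x$fitness$alpha))
  cat(sprintf("  population     : N = %d in %s, seed %d\n",
              x$N, x$true_env, x$seed))
  invisible(x)
}

# condition class so the CLI can map configuration mistakes to exit code 2
config_error <- function(msg) {
  structure(
    class = c("devfeedbacks_config_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
}
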