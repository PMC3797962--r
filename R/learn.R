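#' Bundle a benchmark task set with its primitive configuration
#'
#' The policy-search layer is environment-agnostic: it needs to know how
#' many tasks there are, how many actuator dimensions the synergies have,
#' which basis kind the phase law uses, and how to roll out and score one
#' task.  This constructor wires those up for the three benchmark plants.
#'
#' @param task A [pointmass_task()], [walker_task()] or [arm_task()].
#' @param cfg Optional [primitive_config()] overriding the per-plant
#'   default.
#' @return An object of class `"multitask_env"` with fields `type`, `task`,
#'   `cfg`, `K`, `D`, `kind`.
#' @export
multitask_env <- function(task, cfg = NULL) {
  if (inherits(task, "pointmass_task")) {
    if (is.null(cfg)) {
      cfg <- primitive_config("discrete", alpha_z = 2, beta_z = 0.9,
                              tau = 0.1, g = task$g, dt = task$dt, T = task$T)
    }
    env <- list(type = "pointmass", task = task, cfg = cfg,
                K = task$K, D = 1L, kind = "discrete")
  } else if (inherits(task, "walker_task")) {
    if (is.null(cfg)) {
      cfg <- primitive_config("rhythmic", alpha_z = 2, beta_z = 0.5,
                              tau = 0.06, g = task$g_posture,
                              dt = task$dt, T = task$horizon)
    }
    env <- list(type = "walker", task = task, cfg = cfg,
                K = task$K, D = 4L, kind = "rhythmic")
  } else if (inherits(task, "arm_task")) {
    if (is.null(cfg)) {
      cfg <- primitive_config("discrete", alpha_z = 2, beta_z = 0.9,
                              tau = task$T * task$dt, g = rep(0, task$n_muscles),
                              dt = task$dt, T = task$T)
    }
    env <- list(type = "arm", task = task, cfg = cfg,
                K = task$K, D = task$n_muscles, kind = "discrete")
  } else {
    stop("unsupported task type")
  }
  structure(env, class = "multitask_env")
}

#' @export
print.multitask_env <- function(x, ...) {
  cat(sprintf("<multitask_env> %s | K = %d tasks, D = %d dimension(s), %s\n",
              x$type, x$K, x$D, x$kind))
  invisible(x)
}

# roll out one point-mass task and score it
eval_pointmass_task <- function(env, shapes, coeffs, k, seed) {
  cfg <- env$cfg
  forcing <- function(ph) forcing_synergies(ph, k, shapes, coeffs)
  desired <- rollout_primitive(cfg, forcing)
  res <- pointmass_rollout(env$task, desired, seed = seed)
  as.numeric(viapoint_cost(res, env$task, k))
}

#' Multi-task objective for a flat policy vector
#'
#' Decodes the policy vector through the layout, rolls out every task of
#' the environment, and sums the per-task costs (the total objective
#' \eqn{C(\tau) = \sum_k C(\tau, k)}).  A failed rollout contributes a
#' large finite penalty (`1e6`) rather than raising, so stochastic search
#' never aborts mid-run.
#'
#' @param theta Flat policy vector matching `layout`.
#' @param layout A [parameter_layout()].
#' @param env A [multitask_env()].
#' @param seeds Optional integer vector (one per task) seeding the rollout
#'   noise; `NULL` leaves the RNG stream untouched.
#' @param shapes Fixed synergy shapes, required when
#'   `layout$free_shapes = FALSE`.
#' @return Scalar total cost across tasks.
#' @export
evaluate_multitask <- function(theta, layout, env, seeds = NULL,
                               shapes = NULL) {
  stopifnot(inherits(env, "multitask_env"), layout$K == env$K)
  dec <- unpack_policy(theta, layout, shapes = shapes)
  if (!is.null(seeds)) seeds <- rep_len(seeds, env$K)
  penalty <- 1e6
  if (env$type == "arm") {
    results <- vector("list", env$K)
    for (k in seq_len(env$K)) {
      exc <- forcing_synergies(phase_trace(env$cfg), k, dec$shapes, dec$coeffs)
      results[[k]] <- tryCatch(
        arm_rollout(env$task, exc, cfg = env$cfg),
        error = function(e) NULL)
      if (is.null(results[[k]])) return(penalty)
    }
    return(tryCatch(as.numeric(reaching_cost(results, env$task)),
                    error = function(e) penalty))
  }
  total <- 0
  for (k in seq_len(env$K)) {
    ck <- tryCatch({
      if (env$type == "pointmass") {
        eval_pointmass_task(env, dec$shapes, dec$coeffs, k,
                            seed = if (is.null(seeds)) NULL else seeds[k])
      } else {
        res <- walker_rollout(env$task, dec$shapes, dec$coeffs, k,
                              cfg = env$cfg,
                              seed = if (is.null(seeds)) NULL else seeds[k])
        as.numeric(walker_cost(res, env$task, k))
      }
    }, error = function(e) penalty)
    if (!is.finite(ck)) ck <- penalty
    total <- total + ck
  }
  total
}

# deterministic default starting policy: beta = 0, shifts = 0, unit
# amplitudes, kernel means spread over the phase range, mid-range bandwidth
default_policy <- function(layout) {
  theta <- numeric(layout$total)
  if (layout$free_shapes) {
    N <- layout$N
    grid <- dmp_grid(N, layout$kind)
    trip <- matrix(layout$idx_shape, nrow = 3L)
    n_kernel <- ncol(trip)                # M * D * N kernels, kernel-fastest
    mu_cycle <- rep(grid$means, length.out = n_kernel)
    h_cycle <- rep(grid$bandwidths, length.out = n_kernel)
    theta[trip[1, ]] <- 1
    theta[trip[2, ]] <- mu_cycle
    theta[trip[3, ]] <- log(h_cycle)
  }
  theta
}

#' Learn shared synergies and task coefficients by episodic policy search
#'
#' The main fitting entry point: encodes all task-specific mixing weights
#' (and optionally time shifts) together with the shared synergy shape
#' parameters in one flat policy vector and minimizes the summed episode
#' cost over all tasks with [cma_es()].  Every source of randomness
#' (sampling and rollout noise) is derived from `seed`.
#'
#' @param env A [multitask_env()].
#' @param M Number of shared synergies.
#' @param N Kernels per synergy per dimension.
#' @param scheme Coefficient-sharing scheme (see [task_coefficients()]).
#' @param learn_shifts Are time shifts free parameters?
#' @param budget Number of episode evaluations for the optimizer.
#' @param sigma0 Initial step size of the search distribution.
#' @param seed Integer seed.
#' @param x0 Optional initial flat policy (default: zero weights, unit
#'   amplitudes, kernel means spread over the phase range).
#' @param rollouts_per_eval Episodes averaged per objective evaluation
#'   (default 1, matching per-sample learning-curve accounting).
#' @param lambda Optional CMA population size.
#' @return An object of class `"synergy_fit"`.
#' @export
synergy_learn <- function(env, M = 1L, N = 2L,
                          scheme = c("per_dimension", "time_varying"),
                          learn_shifts = FALSE,
                          budget = 2000L, sigma0 = 0.5, seed = 1L,
                          x0 = NULL, rollouts_per_eval = 1L, lambda = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(env, "multitask_env"))
  layout <- parameter_layout(env$K, M, N, env$D, scheme, learn_shifts,
                             kind = env$kind, free_shapes = TRUE)
  if (is.null(x0)) x0 <- default_policy(layout)
  objective <- function(theta) {
    cost <- 0
    for (r in seq_len(rollouts_per_eval)) {
      seeds <- sample.int(.Machine$integer.max, env$K)
      cost <- cost + evaluate_multitask(theta, layout, env, seeds = seeds)
    }
    cost / rollouts_per_eval
  }
  if (budget <= 0) {
    dec <- unpack_policy(x0, layout)
    return(structure(
      list(par = x0, value = NA_real_, curve = data.frame(),
           layout = layout, shapes = dec$shapes, coeffs = dec$coeffs,
           env = env, seed = seed, budget = 0L, evaluations = 0L,
           frozen_shapes = FALSE),
      class = "synergy_fit"))
  }
  opt <- cma_es(objective, x0, sigma0, budget, lower = layout$lower,
                upper = layout$upper, lambda = lambda, seed = seed)
  dec <- unpack_policy(opt$par, layout)
  structure(
    list(par = opt$par, value = opt$value, curve = opt$curve,
         layout = layout, shapes = dec$shapes, coeffs = dec$coeffs,
         env = env, seed = seed, budget = budget,
         evaluations = opt$evaluations, restarts = opt$restarts,
         frozen_shapes = FALSE),
    class = "synergy_fit")
}

#' Generalize to new tasks with frozen synergies
#'
#' Reuses previously learned synergy shapes as fixed shared knowledge and
#' optimizes only the task-specific block (mixing weights and, when
#' enabled, time shifts) for a new task set.  The number of free
#' parameters equals the task-specific component of [count_parameters()].
#'
#' @param shapes A `"synergy_fit"` or a list of [synergy_shape()]s to
#'   freeze.
#' @param env The (new) [multitask_env()].
#' @param scheme,learn_shifts Coefficient structure for the new tasks.
#' @param budget,sigma0,seed,x0,rollouts_per_eval,lambda As in
#'   [synergy_learn()].
#' @return A `"synergy_fit"` with `frozen_shapes = TRUE`.
#' @export
generalize_fixed_synergies <- function(shapes, env,
                                       scheme = c("per_dimension",
                                                  "time_varying"),
                                       learn_shifts = FALSE,
                                       budget = 500L, sigma0 = 0.5,
                                       seed = 1L, x0 = NULL,
                                       rollouts_per_eval = 1L,
                                       lambda = NULL) {
  scheme <- match.arg(scheme)
  if (inherits(shapes, "synergy_fit")) shapes <- shapes$shapes
  if (inherits(shapes, "synergy_shape")) shapes <- list(shapes)
  M <- length(shapes)
  layout <- parameter_layout(env$K, M, shapes[[1]]$N, env$D, scheme,
                             learn_shifts, kind = env$kind,
                             free_shapes = FALSE)
  stopifnot(layout$total == layout$counts$task_specific)
  if (is.null(x0)) x0 <- numeric(layout$total)
  objective <- function(theta) {
    cost <- 0
    for (r in seq_len(rollouts_per_eval)) {
      seeds <- sample.int(.Machine$integer.max, env$K)
      cost <- cost + evaluate_multitask(theta, layout, env, seeds = seeds,
                                        shapes = shapes)
    }
    cost / rollouts_per_eval
  }
  if (budget <= 0) {
    dec <- unpack_policy(x0, layout, shapes = shapes)
    return(structure(
      list(par = x0, value = NA_real_, curve = data.frame(),
           layout = layout, shapes = shapes, coeffs = dec$coeffs,
           env = env, seed = seed, budget = 0L, evaluations = 0L,
           frozen_shapes = TRUE),
      class = "synergy_fit"))
  }
  opt <- cma_es(objective, x0, sigma0, budget, lower = layout$lower,
                upper = layout$upper, lambda = lambda, seed = seed)
  dec <- unpack_policy(opt$par, layout, shapes = shapes)
  structure(
    list(par = opt$par, value = opt$value, curve = opt$curve,
         layout = layout, shapes = shapes, coeffs = dec$coeffs,
         env = env, seed = seed, budget = budget,
         evaluations = opt$evaluations, restarts = opt$restarts,
         frozen_shapes = TRUE),
    class = "synergy_fit")
}
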