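#' @export
print.synergy_fit <- function(x, ...) {
  cat(sprintf(
    "<synergy_fit> %s | K = %d tasks | M = %d synergies x N = %d kernel(s) x D = %d\n",
    x$env$type, x$layout$K, x$layout$M, x$layout$N, x$layout$D))
  cat(sprintf("  scheme: %s, shifts %s%s\n", x$layout$scheme,
              if (x$layout$learn_shifts) "learned" else "fixed at 0",
              if (x$frozen_shapes) ", shapes frozen" else ""))
  cat(sprintf("  %d free parameters (%d task-specific + %d shared), %d evaluations\n",
              x$layout$total, x$layout$counts$task_specific,
              if (x$frozen_shapes) 0L else x$layout$counts$shared,
              x$evaluations))
  cat(sprintf("  best total cost: %s\n", format(x$value)))
  invisible(x)
}

#' @export
summary.synergy_fit <- function(object, ...) {
  out <- list(fit = object,
              beta = object$coeffs$beta,
              shifts = object$coeffs$shifts,
              best_cost = object$value,
              evaluations = object$evaluations)
  class(out) <- "summary.synergy_fit"
  out
}

#' @export
print.summary.synergy_fit <- function(x, ...) {
  print(x$fit)
  cat("\nTask mixing weights beta (rows: synergies, columns: tasks):\n")
  print(signif(as.matrix(x$beta), 4))
  if (x$fit$layout$learn_shifts) {
    cat("\nTime shifts (phase units):\n")
    print(signif(as.matrix(x$shifts), 4))
  }
  invisible(x)
}

#' Learned parameters of a synergy fit
#'
#' @param object A `"synergy_fit"`.
#' @param ... Unused.
#' @return Named list with `beta`, `shifts` and `shapes`.
#' @export
coef.synergy_fit <- function(object, ...) {
  list(beta = object$coeffs$beta, shifts = object$coeffs$shifts,
       shapes = object$shapes)
}

#' Desired trajectories or excitation patterns of a learned policy
#'
#' Evaluates the learned policy deterministically (no motor noise): for the
#' point-mass and walker environments the primitive's desired trajectories,
#' for the arm the muscle excitation patterns on the phase grid.
#'
#' @param object A `"synergy_fit"`.
#' @param tasks Task indices (default all).
#' @param ... Unused.
#' @return Named list, one element per task: a [rollout_primitive()]
#'   result, or for the arm a T x n_muscles excitation matrix.
#' @export
predict.synergy_fit <- function(object, tasks = NULL, ...) {
  env <- object$env
  if (is.null(tasks)) tasks <- seq_len(env$K)
  out <- lapply(tasks, function(k) {
    if (env$type == "arm") {
      forcing_synergies(phase_trace(env$cfg), k, object$shapes, object$coeffs)
    } else {
      forcing <- function(ph) forcing_synergies(ph, k, object$shapes,
                                                object$coeffs)
      rollout_primitive(env$cfg, forcing)
    }
  })
  names(out) <- paste0("task_", tasks)
  out
}

#' Simulate episodes under a learned policy
#'
#' Full closed-loop (point mass, walker) or open-loop (arm) episodes with
#' the environment's motor noise, reproducible from `seed`.
#'
#' @param object A `"synergy_fit"`.
#' @param nsim Number of episode sets to simulate.
#' @param seed Optional seed.
#' @param tasks Task indices (default all).
#' @param ... Unused.
#' @return List of `nsim` lists of `"episode_result"`s.
#' @export
simulate.synergy_fit <- function(object, nsim = 1, seed = NULL,
                                 tasks = NULL, ...) {
  env <- object$env
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tasks)) tasks <- seq_len(env$K)
  replicate(nsim, simplify = FALSE, {
    lapply(tasks, function(k) {
      if (env$type == "pointmass") {
        forcing <- function(ph) forcing_synergies(ph, k, object$shapes,
                                                  object$coeffs)
        desired <- rollout_primitive(env$cfg, forcing)
        pointmass_rollout(env$task, desired)
      } else if (env$type == "walker") {
        walker_rollout(env$task, object$shapes, object$coeffs, k,
                       cfg = env$cfg)
      } else {
        exc <- forcing_synergies(phase_trace(env$cfg), k, object$shapes,
                                 object$coeffs)
        arm_rollout(env$task, exc, cfg = env$cfg)
      }
    })
  })
}

#' Learning curve plot
#'
#' Best-so-far total cost against the number of episode evaluations.
#'
#' @param x A `"synergy_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.synergy_fit <- function(x, ...) {
  if (nrow(x$curve) == 0) {
    warning("no learning curve recorded (budget 0)")
    return(invisible(x))
  }
  graphics::plot(x$curve$evaluation, x$curve$best_cost, type = "s",
                 xlab = "episode evaluations", ylab = "best total cost", ...)
  graphics::lines(x$curve$evaluation, x$curve$current_cost,
                  col = "grey70")
  invisible(x)
}
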