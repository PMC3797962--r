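#' Point-mass via-point task set
#'
#' A 1 kg point mass must pass through one of five via-points at a given
#' time index and come to rest at the goal.  The mass is driven by the
#' linear feedback law tracking a primitive's desired trajectory, with
#' additive Gaussian motor noise on the control.
#'
#' @param via_points Via-point positions, one per task (default the five
#'   values 0.2, 0.1, 0, -0.1, -0.2).
#' @param t_vp Time index at which each via-point must be met; scalar or
#'   one per task.  Default `round(T / 2)` (the movement midpoint; no value
#'   is prescribed elsewhere).
#' @param g Goal position (default 1).
#' @param T Horizon in steps (default 50).
#' @param dt Step in seconds (default 0.01, i.e. a 0.5 s movement).
#' @param mass Mass in kg.
#' @param sigma Motor-noise standard deviation added to the control
#'   (default 0.5).
#' @param k_pos,k_vel Feedback gains (defaults 400 and 15).
#' @param control_penalty `"squared"` (default) penalizes `sum(u^2)`;
#'   `"as_printed"` penalizes the plain `sum(u)` (which rewards negative
#'   accelerations; kept for fidelity).
#' @return An object of class `"pointmass_task"`.
#' @export
pointmass_task <- function(via_points = c(0.2, 0.1, 0, -0.1, -0.2),
                           t_vp = NULL, g = 1, T = 50L, dt = 0.01,
                           mass = 1, sigma = 0.5,
                           k_pos = 400, k_vel = 15,
                           control_penalty = c("squared", "as_printed")) {
  control_penalty <- match.arg(control_penalty)
  stopifnot(mass > 0, T >= 1)
  if (is.null(t_vp)) t_vp <- round(T / 2)
  t_vp <- rep_len(as.integer(t_vp), length(via_points))
  stopifnot(all(t_vp >= 1), all(t_vp <= T))
  structure(
    list(via_points = via_points, t_vp = t_vp, g = g, T = as.integer(T),
         dt = dt, mass = mass, sigma = sigma, k_pos = k_pos, k_vel = k_vel,
         control_penalty = control_penalty, K = length(via_points)),
    class = "pointmass_task")
}

#' Simulate the point mass tracking a desired trajectory
#'
#' Closed loop: `u_t` from the feedback law, acceleration
#' `(u_t + eta_t) / mass` with `eta_t ~ N(0, sigma^2)`, explicit Euler
#' integration at the task step.  Deterministic given `seed`.
#'
#' @param task A [pointmass_task()].
#' @param desired A [rollout_primitive()] result (D = 1) giving `y*`, `ydot*`.
#' @param seed Optional integer seed for the motor noise.
#' @param y0,yd0 Initial simulated position / velocity (default 0).
#' @return An object of class `"episode_result"` with `y`, `yd` (length T),
#'   `u` (length T - 1), `time`, `phase`, and `task_type = "pointmass"`.
#' @export
pointmass_rollout <- function(task, desired, seed = NULL, y0 = 0, yd0 = 0) {
  stopifnot(inherits(task, "pointmass_task"))
  T <- task$T
  if (nrow(desired$y) < T) stop("desired trajectory shorter than the horizon")
  if (!is.null(seed)) set.seed(seed)
  eta <- if (task$sigma > 0) stats::rnorm(T - 1L, 0, task$sigma) else numeric(T - 1L)
  y <- numeric(T); yd <- numeric(T); u <- numeric(T - 1L)
  y[1] <- y0; yd[1] <- yd0
  for (t in seq_len(T - 1L)) {
    u[t] <- feedback_control(desired$y[t, 1], desired$yd[t, 1],
                             y[t], yd[t], task$k_pos, task$k_vel)
    acc <- (u[t] + eta[t]) / task$mass
    yd[t + 1L] <- yd[t] + task$dt * acc
    y[t + 1L] <- y[t] + task$dt * yd[t]
  }
  structure(
    list(task_type = "pointmass", y = y, yd = yd, u = u,
         time = (seq_len(T) - 1L) * task$dt, phase = desired$phase[seq_len(T)],
         desired = desired),
    class = "episode_result")
}

#' @export
print.episode_result <- function(x, ...) {
  n <- length(x$y %||% x$q[, 1])
  cat(sprintf("<episode_result> %s | %d recorded steps\n", x$task_type, n))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Via-point task cost
#'
#' \deqn{C(k) = 10^5 (y_{t_{vp}} - vp_k)^2
#'   + 10^4 (\dot y_T^2 + 10 (y_T - g)^2) + 5\cdot10^{-4} \sum_t u_t[^2]}
#' The control penalty uses `u^2` or the plain `u` sum depending on the
#' task's `control_penalty` mode.
#'
#' @param result An `"episode_result"` from [pointmass_rollout()].
#' @param task A [pointmass_task()].
#' @param k Task index, selecting via-point and via time.
#' @return Scalar cost; attribute `"terms"` carries the three components.
#' @export
viapoint_cost <- function(result, task, k) {
  stopifnot(inherits(task, "pointmass_task"), k >= 1, k <= task$K)
  T <- task$T
  if (length(result$y) < T) stop("trajectory does not cover the horizon")
  tv <- task$t_vp[k]
  term_vp <- 1e5 * (result$y[tv] - task$via_points[k])^2
  term_goal <- 1e4 * (result$yd[T]^2 + 10 * (result$y[T] - task$g)^2)
  upen <- if (task$control_penalty == "squared") sum(result$u^2) else sum(result$u)
  term_u <- 5e-4 * upen
  structure(term_vp + term_goal + term_u,
            terms = c(via = term_vp, goal = term_goal, control = term_u))
}
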