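#' Simplified muscle-actuated planar arm task set
#'
#' A deliberately simplified stand-in for a musculoskeletal arm: a planar
#' two-link arm (shoulder and elbow hinge joints) driven by six lumped
#' muscles -- mono-articular flexor/extensor pairs at each joint plus one
#' bi-articular pair -- with constant moment arms and force equal to
#' activation times maximum isometric force.  Muscle excitations pass
#' through first-order activation dynamics ([step_activation()]).  The
#' controller is open loop: the synergy forcing is applied directly as the
#' excitation pattern.  Tendon dynamics, muscle wrapping geometry and
#' physiological muscle sets are intentionally out of scope.
#'
#' @param n_targets Number of reaching targets (default 6), placed at
#'   equally spaced directions.
#' @param target_radius Distance of each target from the initial marker
#'   position (m), default 0.15.
#' @param T Horizon in steps (default 500).
#' @param dt Step in seconds (default 0.001; a 500 ms movement).
#' @param lengths Upper-arm and forearm lengths (m).
#' @param masses Segment masses (kg).
#' @param q0 Initial joint angles (shoulder absolute, elbow relative;
#'   radians).
#' @param moment_arms 2 x n_muscles matrix of constant moment arms (m);
#'   rows are shoulder and elbow.
#' @param f_max Maximum isometric force per muscle (N).
#' @param tau_rise,tau_fall Activation time constants (s).
#' @param gravity_compensated If TRUE (default) gravity is cancelled by an
#'   ideal compensation term, so zero excitation keeps the arm at rest.
#' @return An object of class `"arm_task"`.
#' @export
arm_task <- function(n_targets = 6L, target_radius = 0.15,
                     T = 500L, dt = 0.001,
                     lengths = c(0.30, 0.33), masses = c(1.9, 1.5),
                     q0 = c(0.6, 1.3),
                     moment_arms = NULL, f_max = NULL,
                     tau_rise = 0.010, tau_fall = 0.040,
                     gravity_compensated = TRUE) {
  if (is.null(moment_arms)) {
    r <- 0.03
    # sh flex, sh ext, el flex, el ext, bi flex, bi ext
    moment_arms <- rbind(c(r, -r, 0,  0,  r, -r),
                         c(0,  0, r, -r,  r, -r))
  }
  n_mus <- ncol(moment_arms)
  if (is.null(f_max)) f_max <- c(600, 600, 400, 400, 300, 300)[seq_len(n_mus)]
  stopifnot(length(f_max) == n_mus, target_radius > 0)
  L <- lengths; m <- masses; d <- L / 2; I <- m * L^2 / 12
  # marker: wrist position from absolute angles th1, th2 = q1, q1 + q2
  fk <- function(q) {
    th <- c(q[1], q[1] + q[2])
    c(sum(L * cos(th)), sum(L * sin(th)))
  }
  start_marker <- fk(q0)
  ang <- 2 * pi * (seq_len(n_targets) - 1L) / n_targets
  targets <- t(vapply(ang, function(a)
    start_marker + target_radius * c(cos(a), sin(a)), numeric(2)))
  structure(
    list(K = n_targets, targets = targets, target_radius = target_radius,
         start_marker = start_marker, T = as.integer(T), dt = dt,
         L = L, m = m, d = d, I = I, q0 = q0,
         moment_arms = moment_arms, n_muscles = n_mus, f_max = f_max,
         tau_rise = tau_rise, tau_fall = tau_fall,
         gravity_compensated = isTRUE(gravity_compensated), gravity = 9.81,
         fk = fk),
    class = "arm_task")
}

# two-link arm dynamics in joint coordinates (q1 shoulder absolute,
# q2 elbow relative); standard closed form.
arm_accel <- function(q, qd, tau, task) {
  L1 <- task$L[1]; d1 <- task$d[1]; d2 <- task$d[2]
  m1 <- task$m[1]; m2 <- task$m[2]; I1 <- task$I[1]; I2 <- task$I[2]
  a1 <- I1 + m1 * d1^2 + m2 * L1^2
  a2 <- I2 + m2 * d2^2
  a3 <- m2 * L1 * d2
  c2 <- cos(q[2]); s2 <- sin(q[2])
  M <- matrix(c(a1 + a2 + 2 * a3 * c2, a2 + a3 * c2,
                a2 + a3 * c2,          a2), 2, 2)
  Cvec <- c(-a3 * s2 * (2 * qd[1] * qd[2] + qd[2]^2),
            a3 * s2 * qd[1]^2)
  G <- if (task$gravity_compensated) c(0, 0) else {
    gr <- task$gravity
    c(gr * ((m1 * d1 + m2 * L1) * cos(q[1]) + m2 * d2 * cos(q[1] + q[2])),
      gr * m2 * d2 * cos(q[1] + q[2]))
  }
  as.vector(solve(M, tau - Cvec - G))
}

#' Open-loop muscle-driven arm episode
#'
#' Per step: excitations are clipped to [0, 1], passed through the
#' activation dynamics, converted to muscle forces (activation times
#' maximum isometric force), mapped to joint torques through the constant
#' moment-arm matrix, and the two-link dynamics are integrated (RK4).  The
#' marker (wrist) position is recorded at every step.  The rollout is
#' deterministic; `seed` is accepted for interface symmetry with the noisy
#' plants.
#'
#' @param task An [arm_task()].
#' @param excitation T x n_muscles matrix of raw excitation values (the
#'   synergy forcing evaluated on the phase trace), or a function of a
#'   phase vector returning such a matrix together with a
#'   [primitive_config()] via the `cfg` argument.
#' @param cfg Optional discrete [primitive_config()] supplying the phase
#'   trace when `excitation` is a function; also used to record the phase.
#' @param seed Ignored (kept for a uniform rollout signature).
#' @return An `"episode_result"` with joint traces `q`, `qd`, marker
#'   positions `marker` (T x 2), applied `excitation` (raw), clipped
#'   excitations `e`, activations `a`, and `phase`.
#' @export
arm_rollout <- function(task, excitation, cfg = NULL, seed = NULL) {
  stopifnot(inherits(task, "arm_task"))
  T <- task$T
  if (is.null(cfg)) {
    cfg <- primitive_config("discrete", tau = T * task$dt, g = 0,
                            dt = task$dt, T = T)
  }
  ph <- phase_trace(cfg)[seq_len(T)]
  exc <- if (is.function(excitation)) excitation(ph) else excitation
  exc <- as.matrix(exc)
  if (nrow(exc) != T || ncol(exc) != task$n_muscles) {
    stop("excitation must be T x n_muscles")
  }
  e <- pmin(pmax(exc, 0), 1)              # muscle excitations are bounded
  q <- matrix(NA_real_, T, 2); qd <- matrix(NA_real_, T, 2)
  marker <- matrix(NA_real_, T, 2)
  act <- matrix(NA_real_, T, task$n_muscles)
  a <- rep(0, task$n_muscles)
  st_q <- task$q0; st_qd <- c(0, 0)
  h <- task$dt
  for (t in seq_len(T)) {
    q[t, ] <- st_q; qd[t, ] <- st_qd
    marker[t, ] <- task$fk(st_q)
    a <- step_activation(a, e[t, ], h, task$tau_rise, task$tau_fall)
    act[t, ] <- a
    tau <- as.vector(task$moment_arms %*% (a * task$f_max))
    f <- function(qq, qqd) list(dq = qqd, dqd = arm_accel(qq, qqd, tau, task))
    k1 <- f(st_q, st_qd)
    k2 <- f(st_q + h / 2 * k1$dq, st_qd + h / 2 * k1$dqd)
    k3 <- f(st_q + h / 2 * k2$dq, st_qd + h / 2 * k2$dqd)
    k4 <- f(st_q + h * k3$dq, st_qd + h * k3$dqd)
    st_q <- st_q + h / 6 * (k1$dq + 2 * k2$dq + 2 * k3$dq + k4$dq)
    st_qd <- st_qd + h / 6 * (k1$dqd + 2 * k2$dqd + 2 * k3$dqd + k4$dqd)
  }
  structure(
    list(task_type = "arm", q = q, qd = qd, marker = marker,
         excitation = exc, e = e, a = act, phase = ph,
         time = (seq_len(T) - 1L) * task$dt),
    class = "episode_result")
}

#' Multi-directional reaching cost
#'
#' Total multi-task objective: for each task k the time-averaged Euclidean
#' marker-to-target distance (weight 3) plus a quadratic excitation
#' penalty integrated over the phase interval,
#' \deqn{C = \sum_k \Big[ 3 \tfrac1T \sum_t \|g_k - v_k(t)\|
#'   + 10^{-3} \int_0^1 f(s,k)^\top f(s,k)\, ds \Big],}
#' the integral approximated by the trapezoidal rule on the recorded phase
#' grid (the raw, unclipped forcing is penalized).
#'
#' @param results List of K `"episode_result"`s from [arm_rollout()], in
#'   task order.
#' @param task An [arm_task()].
#' @return Scalar total cost; attribute `"per_task"` carries the K
#'   per-task values and attribute `"terms"` the distance/effort split.
#' @export
reaching_cost <- function(results, task) {
  stopifnot(inherits(task, "arm_task"))
  if (length(results) != task$K) stop("need one episode result per task")
  per_task <- numeric(task$K); dist_t <- numeric(task$K); eff_t <- numeric(task$K)
  for (k in seq_len(task$K)) {
    res <- results[[k]]
    if (is.null(res$marker) || is.null(res$excitation)) {
      stop("episode result lacks marker or excitation records")
    }
    dv <- sweep(res$marker, 2, task$targets[k, ])
    dist_t[k] <- 3 * mean(sqrt(rowSums(dv^2)))
    ff <- rowSums(res$excitation^2)
    s <- res$phase
    # trapezoid over the (decreasing) phase grid
    eff_t[k] <- 1e-3 * abs(sum(diff(s) * (ff[-1] + ff[-length(ff)]) / 2))
    per_task[k] <- dist_t[k] + eff_t[k]
  }
  structure(sum(per_task), per_task = per_task,
            terms = c(distance = sum(dist_t), effort = sum(eff_t)))
}
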