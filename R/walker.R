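#' Planar five-link biped walker task set
#'
#' A torso and two legs (thigh + shank each) walking in the sagittal plane
#' on flat ground.  Only the four hip and knee joints are actuated; the
#' absolute orientation is not.  The stance foot is modelled as a pin
#' joint; when the swing foot touches the ground an instantaneous inelastic
#' impact is applied and the legs swap roles (hybrid dynamics).  The
#' multi-task objective rewards travelled distance and episode duration and
#' penalizes deviations of per-step swing-foot clearance from a desired
#' step height, one desired height per task.
#'
#' The physical parameters (masses, lengths, limits, gains, initial state)
#' are documented synthetic defaults in the style of standard planar
#' five-link walker models; they are fixtures of this package, not
#' reference values.
#'
#' Internally the configuration is the vector of five absolute link angles
#' `theta` (stance shank, stance thigh, torso, swing thigh, swing shank,
#' measured from the positive x-axis, each link oriented from its proximal
#' joint to its distal end).  The reported coordinates are
#' `q1 = theta2 - theta3` (stance hip), `q2 = theta4 - theta3` (swing hip),
#' `q3 = theta1 - theta2` (stance knee), `q4 = theta5 - theta4` (swing
#' knee), `q5 = theta3` (torso reference angle to the ground).
#'
#' @param r_star Desired step heights (m), one per task.
#' @param dt Integration step (s), default 0.002.
#' @param horizon Maximum number of steps, default 5000 (10 s).
#' @param sigma Motor-noise standard deviation added to each joint torque.
#' @param gravity Gravitational acceleration (m/s^2); set 0 for
#'   equilibrium tests.
#' @param lengths Named vector: `shank`, `thigh`, `torso` link lengths (m).
#' @param masses Named vector: link masses (kg), same names.
#' @param q_min,q_max Joint-limit box on the reported coordinates
#'   (q1..q5); the episode ends when the state leaves it.
#' @param k_pos,k_vel Feedback gains for the four actuated joints.
#' @param theta0,thetad0 Initial absolute link angles and velocities.
#' @param g_posture Attractor point (goal posture) for the four actuated
#'   joint angles used by rhythmic primitives.
#' @param contact_sep Minimum horizontal stance-to-swing foot separation
#'   (m) for a ground contact to count as a heel strike.
#' @return An object of class `"walker_task"` with precomputed dynamics
#'   coefficient matrices.
#' @export
walker_task <- function(r_star = c(0.15, 0.2, 0.25, 0.3),
                        dt = 0.002, horizon = 5000L, sigma = 1,
                        gravity = 9.81,
                        lengths = c(shank = 0.4, thigh = 0.4, torso = 0.625),
                        masses = c(shank = 3.2, thigh = 6.8, torso = 12),
                        q_min = c(-2.6, -2.6, -2.8, -2.8, 0.6),
                        q_max = c(2.6, 2.6, 2.8, 2.8, 2.6),
                        k_pos = rep(240, 4), k_vel = rep(12, 4),
                        theta0 = c(1.45, 1.5, 1.57, -1.9, -1.25),
                        thetad0 = c(-0.9, -0.9, 0, 1.6, 1.6),
                        g_posture = NULL,
                        contact_sep = 0.05) {
  Ls <- lengths[["shank"]]; Lt <- lengths[["thigh"]]; Lb <- lengths[["torso"]]
  ms <- masses[["shank"]]; mt <- masses[["thigh"]]; mb <- masses[["torso"]]
  L <- c(Ls, Lt, Lb, Lt, Ls)              # per link 1..5
  m <- c(ms, mt, mb, mt, ms)
  d <- L / 2                              # mid-link centres of mass
  I <- m * L^2 / 12                       # slender-rod inertia about CoM
  # CoM position coefficients: p_i = foot + sum_j Cm[i, j] * e(theta_j)
  Cm <- rbind(c(d[1], 0,    0,    0,    0),
              c(L[1], d[2], 0,    0,    0),
              c(L[1], L[2], d[3], 0,    0),
              c(L[1], L[2], 0,    d[4], 0),
              c(L[1], L[2], 0,    L[4], d[5]))
  A <- t(Cm) %*% (m * Cm)                 # mass-matrix coefficients
  b <- as.vector(m %*% Cm)                # gravity coefficients
  Fsw <- c(L[1], L[2], 0, L[4], L[5])     # swing-foot position coefficients
  # torque map: columns q1..q4 (stance hip, swing hip, stance knee, swing knee)
  B <- matrix(0, 5, 4)
  B[2, 1] <- 1; B[3, 1] <- -1
  B[4, 2] <- 1; B[3, 2] <- -1
  B[1, 3] <- 1; B[2, 3] <- -1
  B[5, 4] <- 1; B[4, 4] <- -1
  if (is.null(g_posture)) {
    th <- theta0
    g_posture <- c(th[2] - th[3], th[4] - th[3] + pi, th[1] - th[2],
                   th[5] - th[4])
  }
  structure(
    list(r_star = r_star, K = length(r_star), dt = dt,
         horizon = as.integer(horizon), sigma = sigma, gravity = gravity,
         L = L, m = m, d = d, I = I, Cm = Cm, A = A, b = b, Fsw = Fsw, B = B,
         q_min = q_min, q_max = q_max, k_pos = k_pos, k_vel = k_vel,
         theta0 = theta0, thetad0 = thetad0, g_posture = g_posture,
         contact_sep = contact_sep),
    class = "walker_task")
}

#' Initial walker state
#'
#' @param task A [walker_task()].
#' @return List with `theta`, `thetad`, `foot_x` (stance foot x-position).
#' @export
walker_init <- function(task) {
  list(theta = task$theta0, thetad = task$thetad0, foot_x = 0)
}

#' Reported walker coordinates
#'
#' Maps the internal absolute link angles to the reported joint/reference
#' angles q1..q5 (see [walker_task()]) and their velocities.
#'
#' @param state Walker state list.
#' @param task A [walker_task()].
#' @return List with `q`, `qd` (length 5), `hip` (x, y), `swing_foot`
#'   (x, y), `swing_foot_vy`.
#' @export
walker_coords <- function(state, task) {
  th <- state$theta; thd <- state$thetad
  # swing thigh points hip->knee (down), torso points up: + pi so that a
  # straight-hanging swing leg reads ~0 like the stance side
  q <- c(th[2] - th[3], th[4] - th[3] + pi, th[1] - th[2], th[5] - th[4],
         th[3])
  q <- (q + pi) %% (2 * pi) - pi          # principal value after relabelling
  qd <- c(thd[2] - thd[3], thd[4] - thd[3], thd[1] - thd[2],
          thd[5] - thd[4], thd[3])
  hip <- c(state$foot_x, 0) +
    c(sum(task$L[1:2] * cos(th[1:2])), sum(task$L[1:2] * sin(th[1:2])))
  swf <- c(state$foot_x, 0) +
    c(sum(task$Fsw * cos(th)), sum(task$Fsw * sin(th)))
  vy <- sum(task$Fsw * cos(th) * thd)
  list(q = q, qd = qd, hip = hip, swing_foot = swf, swing_foot_vy = vy)
}

walker_accel <- function(theta, thetad, tau_gen, task) {
  dth <- outer(theta, theta, "-")
  M <- task$A * cos(dth) + diag(task$I)
  Cvec <- (task$A * sin(dth)) %*% (thetad^2)
  G <- task$gravity * task$b * cos(theta)
  as.vector(solve(M, tau_gen - Cvec - G))
}

#' Total mechanical energy of the walker
#'
#' Kinetic plus gravitational potential energy of the pinned five-link
#' chain; conserved in the torque-free, impact-free case.
#'
#' @param state Walker state list.
#' @param task A [walker_task()].
#' @return Scalar energy in joules.
#' @export
walker_energy <- function(state, task) {
  th <- state$theta; thd <- state$thetad
  M <- task$A * cos(outer(th, th, "-")) + diag(task$I)
  0.5 * sum(thd * (M %*% thd)) + task$gravity * sum(task$b * sin(th))
}

# rows of the angular-momentum matrix H (H %*% thetad = momentum) for a
# link set S about point P; `coef` gives the velocity Jacobian coefficients
# (old chain: Cm; new chain: sweep(Cm, 2, Fsw)).
ang_mom_matrix <- function(theta, task, coef, P_coef, S, origin) {
  # positions of CoMs relative to P: (Cm[i, ] - P_coef) e(theta)
  ct <- cos(theta); st <- sin(theta)
  H <- numeric(5)
  for (j in 1:5) {
    hj <- 0
    for (i in S) {
      rel <- task$Cm[i, ] - P_coef
      rx <- sum(rel * ct); ry <- sum(rel * st)
      # Jacobian column j of p_i: coef[i, j] * (-sin, cos)
      jx <- -coef[i, j] * st[j]; jy <- coef[i, j] * ct[j]
      hj <- hj + task$m[i] * (rx * jy - ry * jx)
    }
    if (j %in% S) hj <- hj + task$I[j]
    H[j] <- hj
  }
  H
}

#' Inelastic impact map at heel strike
#'
#' Computes the post-impact angular velocities when the swing foot becomes
#' the new pin joint, from conservation of angular momentum of the whole
#' robot about the new contact point and of each distal sub-chain about its
#' connecting joint, then swaps the leg labels.  The impact never increases
#' kinetic energy.
#'
#' @param state Pre-impact walker state.
#' @param task A [walker_task()].
#' @return Post-impact state in the relabelled (new stance leg) coordinates.
#' @export
walker_impact <- function(state, task) {
  th <- state$theta; thd <- state$thetad
  swf <- walker_coords(state, task)$swing_foot
  Fsw <- task$Fsw
  # (P_coef, S) pairs in swing-foot-pinned chain: contact/all, swing-knee/
  # all-but-swing-shank, hip/torso, hip/old-stance-leg, old-stance-knee/
  # old-stance-shank
  specs <- list(
    list(P = Fsw,                     S = 1:5),
    list(P = c(task$L[1], task$L[2], 0, task$L[4], 0), S = c(1, 2, 3, 4)),
    list(P = c(task$L[1], task$L[2], 0, 0, 0),         S = 3L),
    list(P = c(task$L[1], task$L[2], 0, 0, 0),         S = c(1L, 2L)),
    list(P = c(task$L[1], 0, 0, 0, 0),                 S = 1L))
  coef_old <- task$Cm
  coef_new <- sweep(task$Cm, 2, Fsw)
  Hpre <- t(vapply(specs, function(sp)
    ang_mom_matrix(th, task, coef_old, sp$P, sp$S, state$foot_x), numeric(5)))
  Hpost <- t(vapply(specs, function(sp)
    ang_mom_matrix(th, task, coef_new, sp$P, sp$S, state$foot_x), numeric(5)))
  thd_plus <- as.vector(solve(Hpost, Hpre %*% thd))
  # relabel: old swing leg becomes the new stance leg; link directions flip
  perm <- c(5, 4, 3, 2, 1)
  theta_new <- th[perm] + c(pi, pi, 0, pi, pi)
  thetad_new <- thd_plus[perm]
  list(theta = theta_new, thetad = thetad_new, foot_x = swf[1])
}

#' One integration step of the walker
#'
#' Fixed-step RK4 on the pinned five-link dynamics, followed by ground
#' contact detection (swing-foot height crossing zero with downward
#' velocity at sufficient horizontal separation from the stance foot).  On
#' contact the inelastic [walker_impact()] map is applied instantaneously
#' and the legs swap roles.
#'
#' @param state Walker state list (`theta`, `thetad`, `foot_x`).
#' @param torques Torque vector for the four actuated joints.
#' @param task A [walker_task()].
#' @return List with `state` (post-step, possibly post-impact) and
#'   `impact` (logical).
#' @export
walker_step <- function(state, torques, task) {
  tau_gen <- as.vector(task$B %*% torques)
  h <- task$dt
  f <- function(th, thd) list(dth = thd,
                              dthd = walker_accel(th, thd, tau_gen, task))
  k1 <- f(state$theta, state$thetad)
  k2 <- f(state$theta + h / 2 * k1$dth, state$thetad + h / 2 * k1$dthd)
  k3 <- f(state$theta + h / 2 * k2$dth, state$thetad + h / 2 * k2$dthd)
  k4 <- f(state$theta + h * k3$dth, state$thetad + h * k3$dthd)
  new <- list(
    theta = state$theta + h / 6 * (k1$dth + 2 * k2$dth + 2 * k3$dth + k4$dth),
    thetad = state$thetad +
      h / 6 * (k1$dthd + 2 * k2$dthd + 2 * k3$dthd + k4$dthd),
    foot_x = state$foot_x)
  y_prev <- walker_coords(state, task)$swing_foot[2]
  co <- walker_coords(new, task)
  impact <- y_prev > 1e-9 && co$swing_foot[2] <= 0 && co$swing_foot_vy < 0 &&
    abs(co$swing_foot[1] - new$foot_x) > task$contact_sep
  if (impact) new <- walker_impact(new, task)
  list(state = new, impact = impact)
}

#' Closed-loop walker episode with phase resetting
#'
#' Runs the full pipeline for one task: a rhythmic primitive (synergy
#' forcing, attractor system) generates desired joint trajectories, the
#' linear feedback law with additive Gaussian torque noise drives the
#' walker, and at every heel strike the rhythmic phase is reset to zero so
#' that the gait cycle synchronizes with ground contact.  The episode ends
#' at the horizon or when the reported coordinates leave the joint-limit
#' box.
#'
#' @param task A [walker_task()].
#' @param shapes List of M rhythmic [synergy_shape()]s with D = 4, or NULL
#'   for an unforced primitive.
#' @param coeffs Matching [task_coefficients()] (ignored when `shapes` is
#'   NULL).
#' @param k Task index.
#' @param cfg Optional [primitive_config()] (rhythmic, D = 4); default uses
#'   alpha_z = 2, beta_z = 0.5, tau = 0.06 and the task posture goal.
#' @param seed Optional seed for the torque noise.
#' @return An `"episode_result"` with the state/torque traces, phase trace,
#'   impact flags, hip x-coordinates, per-step maximal swing-foot heights
#'   `r`, step count `S`, and realized horizon `T`.
#' @export
walker_rollout <- function(task, shapes = NULL, coeffs = NULL, k = 1L,
                           cfg = NULL, seed = NULL) {
  stopifnot(inherits(task, "walker_task"))
  if (is.null(cfg)) {
    cfg <- primitive_config("rhythmic", alpha_z = 2, beta_z = 0.5,
                            tau = 0.06, g = task$g_posture,
                            dt = task$dt, T = task$horizon)
  }
  stopifnot(cfg$kind == "rhythmic", cfg$D == 4L)
  if (!is.null(seed)) set.seed(seed)
  state <- walker_init(task)
  co <- walker_coords(state, task)
  att <- list(y = co$q[1:4], z = cfg$tau * co$qd[1:4],
              yd = co$qd[1:4])
  phi <- 0
  Tmax <- task$horizon
  q <- matrix(NA_real_, Tmax, 5); qd <- matrix(NA_real_, Tmax, 5)
  u <- matrix(NA_real_, Tmax, 4)
  phase <- numeric(Tmax); impacts <- logical(Tmax); hip_x <- numeric(Tmax)
  swf_y <- numeric(Tmax)
  r <- numeric(0); max_h <- 0
  t_end <- Tmax
  for (t in seq_len(Tmax)) {
    co <- walker_coords(state, task)
    q[t, ] <- co$q; qd[t, ] <- co$qd
    phase[t] <- phi; hip_x[t] <- co$hip[1]; swf_y[t] <- co$swing_foot[2]
    if (any(co$q < task$q_min) || any(co$q > task$q_max)) {
      t_end <- t
      break
    }
    max_h <- max(max_h, co$swing_foot[2])
    f <- if (is.null(shapes)) rep(0, 4) else
      as.vector(forcing_synergies(phi, k, shapes, coeffs))
    ut <- feedback_control(att$y, att$yd, co$q[1:4], co$qd[1:4],
                           task$k_pos, task$k_vel)
    u[t, ] <- ut
    noise <- if (task$sigma > 0) stats::rnorm(4, 0, task$sigma) else rep(0, 4)
    res <- walker_step(state, ut + noise, task)
    state <- res$state
    impacts[t] <- res$impact
    if (res$impact) {
      r <- c(r, max_h)
      max_h <- 0
      phi <- 0                            # phase resetting at heel strike
      att <- list(y = att$y, z = att$z, yd = att$yd)
    } else {
      phi <- step_phase(phi, cfg)
    }
    att <- step_attractor(att, f, cfg)
    if (t == Tmax) t_end <- Tmax
  }
  keep <- seq_len(t_end)
  structure(
    list(task_type = "walker", q = q[keep, , drop = FALSE],
         qd = qd[keep, , drop = FALSE], u = u[keep, , drop = FALSE],
         phase = phase[keep], impact = impacts[keep],
         hip_x = hip_x[keep], swing_foot_y = swf_y[keep],
         r = r, S = length(r), T = t_end,
         x1 = hip_x[1], xT = hip_x[t_end],
         time = (keep - 1L) * task$dt, dt = task$dt),
    class = "episode_result")
}

#' Walker task cost
#'
#' \deqn{C(k) = -0.6\,(x_T - x_1) + 0.2\,(5 - T\,\Delta t)
#'   + 50 \sum_{i=1}^{S} (r_i - r^*_k)^2}
#' Distance travelled is rewarded (negative term), early termination and
#' step-height deviations are penalized.
#'
#' @param result An `"episode_result"` from [walker_rollout()].
#' @param task A [walker_task()].
#' @param k Task index selecting the desired step height.
#' @return Scalar cost; attribute `"terms"` carries the three components.
#' @export
walker_cost <- function(result, task, k) {
  stopifnot(inherits(task, "walker_task"), k >= 1, k <= task$K)
  for (fld in c("x1", "xT", "T", "r")) {
    if (is.null(result[[fld]])) stop("episode result lacks field ", fld)
  }
  term_dist <- -0.6 * (result$xT - result$x1)
  term_time <- 0.2 * (5 - result$T * task$dt)
  term_step <- 50 * sum((result$r - task$r_star[k])^2)
  structure(term_dist + term_time + term_step,
            terms = c(distance = term_dist, duration = term_time,
                      step_height = term_step))
}
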