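test_that("gravity-free walker with zero velocity is in equilibrium", {
  task <- walker_task(gravity = 0, sigma = 0)
  st <- walker_init(task)
  st$thetad <- rep(0, 5)
  res <- walker_step(st, rep(0, 4), task)
  expect_equal(res$state$theta, st$theta, tolerance = 1e-12)
  expect_equal(res$state$thetad, rep(0, 5))
  expect_false(res$impact)
})

test_that("torque-free mechanical energy is conserved by the integrator", {
  task <- walker_task(sigma = 0, contact_sep = Inf)  # contacts disabled
  st <- walker_init(task)
  E0 <- walker_energy(st, task)
  drift <- 0
  for (t in 1:250) {                    # 0.5 s at dt = 2 ms
    res <- walker_step(st, rep(0, 4), task)
    expect_false(res$impact)
    st <- res$state
    drift <- max(drift, abs(walker_energy(st, task) - E0))
  }
  expect_lt(drift / abs(E0), 1e-3)
})

test_that("impact map conserves angular momentum about the contact point", {
  task <- walker_task(sigma = 0)
  # configuration with the swing foot exactly on the ground: solve the
  # swing-shank angle from the chain height closure
  th <- c(1.2, 1.2, 1.57, -1.75, NA)
  h_rest <- sum(task$Fsw[1:4] * sin(th[1:4]))
  th[5] <- asin(-h_rest / task$L[5])
  st <- list(theta = th, thetad = rep(0, 5), foot_x = 0)
  expect_lt(abs(walker_coords(st, task)$swing_foot[2]), 1e-12)
  set.seed(5)
  for (rep in 1:5) {
    st$thetad <- rnorm(5, 0, 1)
    pre <- st
    post <- walker_impact(pre, task)
    P <- walker_coords(pre, task)$swing_foot     # new contact point
    # independent oracle: CoM positions by forward kinematics, velocities
    # by finite differences along the flow of each (pinned) chain
    eps <- 1e-7
    H_of <- function(state, origin) {
      p0 <- walker_com_positions(state$theta - eps * state$thetad, task, origin)
      p1 <- walker_com_positions(state$theta + eps * state$thetad, task, origin)
      p <- (p0 + p1) / 2
      v <- (p1 - p0) / (2 * eps)
      H <- 0
      for (i in 1:5) {
        r <- p[i, ] - P
        H <- H + task$m[i] * (r[1] * v[i, 2] - r[2] * v[i, 1]) +
          task$I[i] * state$thetad[i]
      }
      H
    }
    H_pre <- H_of(pre, c(pre$foot_x, 0))
    H_post <- H_of(post, c(post$foot_x, 0))
    expect_equal(H_post, H_pre, tolerance = 1e-6)
    # inelastic impact never increases kinetic energy
    ke <- function(state) {
      M <- task$A * cos(outer(state$theta, state$theta, "-")) + diag(task$I)
      0.5 * sum(state$thetad * (M %*% state$thetad))
    }
    expect_lte(ke(post), ke(pre) + 1e-10)
    # relabelling preserves the spatial configuration (hip position)
    expect_equal(walker_coords(post, task)$hip,
                 walker_coords(pre, task)$hip, tolerance = 1e-12)
  }
})

test_that("closed-loop rollout resets the phase at every heel strike", {
  task <- walker_task(sigma = 0)
  res <- walker_rollout(task, seed = 1)  # PD toward posture, no synergies
  expect_gt(res$S, 0)                    # episode contains heel strikes
  hits <- which(res$impact)
  hits <- hits[hits < res$T]
  expect_true(all(res$phase[hits + 1L] == 0))
  # sawtooth: strictly increasing between impacts
  cfg_rate <- task$dt / 0.06
  incr <- diff(res$phase)
  expect_true(all(incr[!res$impact[-res$T]] > 0))
  expect_equal(unique(round(incr[!res$impact[-res$T]], 12)),
               round(cfg_rate, 12))
  expect_equal(res$S, length(res$r))
})

test_that("rollouts are reproducible and joint-limit violations end the episode", {
  task <- walker_task()                  # sigma = 1
  r1 <- walker_rollout(task, seed = 42)
  r2 <- walker_rollout(task, seed = 42)
  expect_identical(r1$q, r2$q)
  expect_identical(r1$r, r2$r)
  # an initial state far outside the limits terminates immediately
  task_bad <- walker_task(sigma = 0, theta0 = c(1.45, 1.5, 0.3, -1.9, -1.25))
  res <- walker_rollout(task_bad, seed = 1)
  expect_lte(res$T, 2)
  expect_equal(res$S, 0)
})

test_that("walker cost matches hand-computed values", {
  task <- walker_task()
  mk <- function(x1, xT, T, r) {
    structure(list(task_type = "walker", x1 = x1, xT = xT, T = T, r = r),
              class = "episode_result")
  }
  # 2 m in a full 5 s episode with perfect step heights (k = 2: r* = 0.2)
  full <- mk(0, 2, 2500, rep(0.2, 8))
  expect_equal(as.numeric(walker_cost(full, task, 2)), -1.2)
  # instant fall: T = 1, no displacement, no steps
  fall <- mk(0, 0, 1, numeric(0))
  expect_equal(as.numeric(walker_cost(fall, task, 1)), 0.2 * (5 - 0.002))
  # step-height deviations enter quadratically with weight 50
  dev <- mk(0, 0, 2500, c(0.25, 0.15))
  expect_equal(as.numeric(walker_cost(dev, task, 2)), 50 * 2 * 0.05^2)
})

test_that("episode cost accounting is consistent with the recorded episode", {
  task <- walker_task(sigma = 0)
  res <- walker_rollout(task, seed = 3)
  for (k in 1:4) {
    expected <- -0.6 * (res$xT - res$x1) + 0.2 * (5 - res$T * task$dt) +
      50 * sum((res$r - task$r_star[k])^2)
    expect_equal(as.numeric(walker_cost(res, task, k)), expected)
  }
})
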