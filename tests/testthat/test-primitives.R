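test_that("discrete phase follows the exponential decay law as dt shrinks", {
  # closed form s(t) = exp(-alpha_s t / tau); Euler must converge to it
  errs <- vapply(c(1e-3, 1e-4, 1e-5), function(dt) {
    cfg <- primitive_config("discrete", tau = 0.1, alpha_s = 2,
                            dt = dt, T = round(0.1 / dt) + 1L)
    s_end <- phase_trace(cfg)[cfg$T]
    abs(s_end - exp(-2))
  }, numeric(1))
  expect_lt(errs[3], 1e-4)
  expect_true(all(diff(errs) < 0))          # O(dt) convergence
  # stepping stays positive and strictly decreasing
  cfg <- primitive_config("discrete", tau = 0.1, alpha_s = 2, dt = 0.01,
                          T = 50L)
  tr <- phase_trace(cfg)
  expect_true(all(tr > 0))
  expect_true(all(diff(tr) < 0))
  expect_equal(step_phase(tr[1], cfg), tr[2])
})

test_that("rhythmic phase advances by exactly dt / tau per step", {
  cfg <- primitive_config("rhythmic", tau = 0.06, dt = 0.002, T = 31L)
  tr <- phase_trace(cfg)
  expect_equal(diff(tr), rep(cfg$dt / cfg$tau, 30))
  # phi(t) = t / tau: after time 0.06, phi = 1
  cfg2 <- primitive_config("rhythmic", tau = 0.06, dt = 0.001, T = 61L)
  expect_equal(phase_trace(cfg2)[61], 1)
})

test_that("default alpha_s brings the phase to about 0.01 at the horizon", {
  cfg <- primitive_config("discrete", tau = 0.1, dt = 0.01, T = 50L)
  t_end <- cfg$T * cfg$dt
  expect_equal(exp(-cfg$alpha_s * t_end / cfg$tau), 0.01, tolerance = 1e-12)
})

test_that("classical forcing: normalization cancels identical weights", {
  for (kind in c("discrete", "rhythmic")) {
    w <- dmp_weights(rep(3.7, 5), kind)
    x <- if (kind == "discrete") seq(0.05, 1, length.out = 9) else
      seq(0, 2 * pi, length.out = 9)
    f <- forcing_dmp(x, w)
    expect_equal(as.vector(f), if (kind == "discrete") 3.7 * x else
      rep(3.7, 9), tolerance = 1e-12)
    expect_equal(as.vector(forcing_dmp(x, dmp_weights(rep(0, 5), kind))),
                 rep(0, 9))
  }
  # single basis: normalizer is the kernel itself
  w1 <- dmp_weights(3, "discrete")
  expect_equal(as.vector(forcing_dmp(0.2, w1)), 0.6)
})

test_that("attractor fixed point and hand-computed Euler step", {
  cfg <- primitive_config("discrete", alpha_z = 2, beta_z = 0.9, tau = 0.1,
                          g = 1, dt = 0.01, T = 50L)
  at_goal <- list(y = 1, z = 0)
  stepped <- step_attractor(at_goal, 0, cfg)
  expect_equal(stepped$y, 1)
  expect_equal(stepped$z, 0)
  # from rest at 0: zdot = alpha_z * beta_z * g / tau = 18, z = dt * 18
  s0 <- list(y = 0, z = 0)
  s1 <- step_attractor(s0, 0, cfg)
  expect_equal(s1$z, 0.18)
  expect_equal(s1$y, 0)
  expect_equal(s1$yd, 1.8)
})

test_that("unforced rollout matches the matrix-exponential closed form and reaches the goal", {
  cfg <- primitive_config("discrete", alpha_z = 2, beta_z = 0.9, tau = 0.1,
                          g = 1, dt = 1e-3, T = 1001L)
  ro_euler <- rollout_primitive(cfg)
  ro_rk4 <- rollout_primitive(cfg, method = "rk4")
  ref <- attractor_closed_form(cfg, ro_euler$time)
  expect_lt(max(abs(ro_rk4$y[, 1] - ref[, 1])), 1e-9)
  expect_lt(max(abs(ro_euler$y[, 1] - ref[, 1])), 1e-2)
  expect_lt(abs(ro_euler$y[cfg$T, 1] - 1), 1e-3)
  # Euler converges to the closed form at first order
  err_at <- vapply(c(1e-3, 2.5e-4), function(dt) {
    cfgd <- primitive_config("discrete", alpha_z = 2, beta_z = 0.9,
                             tau = 0.1, g = 1, dt = dt,
                             T = round(1 / dt) + 1L)
    ro <- rollout_primitive(cfgd)
    max(abs(ro$y[, 1] - attractor_closed_form(cfgd, ro$time)[, 1]))
  }, numeric(1))
  expect_gt(err_at[1] / err_at[2], 3)       # ~4x for a first-order scheme
})

test_that("rhythmic unforced rollout stays at the goal; rollouts are deterministic", {
  cfg <- primitive_config("rhythmic", g = 0.4, tau = 0.06, dt = 0.002,
                          T = 200L, y0 = 0.4, z0 = 0)
  ro <- rollout_primitive(cfg)
  expect_equal(ro$y[, 1], rep(0.4, 200))
  cfg2 <- primitive_config("discrete", g = 1, dt = 0.01, T = 50L)
  f <- function(ph) matrix(sin(8 * ph), ncol = 1)
  expect_identical(rollout_primitive(cfg2, f), rollout_primitive(cfg2, f))
})

test_that("synergy forcing reduces correctly in limiting cases", {
  sh <- random_shape("discrete", N = 2, D = 3, seed = 11)
  s <- seq(0.02, 1, length.out = 25)
  co0 <- task_coefficients("per_dimension", beta = array(0, c(1, 4, 3)))
  f0 <- forcing_synergies(s, 2, list(sh), co0)
  expect_equal(f0, matrix(0, 25, 3))
  # M = 1, beta = 1, no shift: equals eval_synergy * s per dimension
  co1 <- task_coefficients("per_dimension", beta = array(1, c(1, 1, 3)))
  f1 <- forcing_synergies(s, 1, list(sh), co1)
  for (d in 1:3) expect_equal(f1[, d], eval_synergy(s, sh, d) * s)
  # rhythmic kind carries no trailing phase factor
  shr <- random_shape("rhythmic", N = 2, D = 2, seed = 12)
  cor1 <- task_coefficients("per_dimension", beta = array(1, c(1, 1, 2)))
  fr <- forcing_synergies(0.9, 1, list(shr), cor1)
  expect_equal(fr[1, 1], eval_synergy(0.9, shr, 1))
})

test_that("time-varying scheme equals per-dimension scheme with tied coefficients", {
  for (seed in 1:5) {
    set.seed(seed)
    M <- 2; K <- 3; D <- 4
    shapes <- lapply(1:M, function(m) random_shape("discrete", 3, D,
                                                   seed = 40 + seed * M + m))
    beta <- matrix(rnorm(M * K), M, K)
    delta <- matrix(runif(M * K, -0.2, 0.2), M, K)
    tv <- task_coefficients("time_varying", beta, delta, learn_shifts = TRUE)
    pd <- task_coefficients("per_dimension",
                            beta = array(rep(beta, D), c(M, K, D)),
                            shifts = array(rep(delta, D), c(M, K, D)),
                            learn_shifts = TRUE)
    s <- seq(0, 1, length.out = 30)
    for (k in 1:K) {
      expect_equal(forcing_synergies(s, k, shapes, tv),
                   forcing_synergies(s, k, shapes, pd), tolerance = 1e-13)
    }
  }
})

test_that("synergy forcing is linear in the mixing weights", {
  shapes <- lapply(1:2, function(m) random_shape("discrete", 2, 2, seed = 60 + m))
  s <- seq(0, 1, length.out = 15)
  b1 <- matrix(rnorm(2), 2, 1); b2 <- matrix(rnorm(2), 2, 1)
  f <- function(b) forcing_synergies(s, 1, shapes,
                                     task_coefficients("time_varying", b))
  expect_equal(f(2 * b1 + 3 * b2), 2 * f(b1) + 3 * f(b2), tolerance = 1e-12)
})

test_that("classical primitives are an exact special case of the synergy representation", {
  for (kind in c("discrete", "rhythmic")) {
    for (seed in 1:20) {
      set.seed(1000 + seed)
      N <- sample(1:6, 1)
      w <- dmp_weights(rnorm(N), kind)
      sc <- dmp_as_special_case(w)
      x <- if (kind == "discrete") seq(0, 1, length.out = 50) else
        seq(0, 2 * pi, length.out = 50)
      f_syn <- forcing_synergies(x, 1, sc$shapes, sc$coeffs)
      f_dmp <- forcing_dmp(x, w, normalize = FALSE)
      expect_lt(max(abs(f_syn - f_dmp)), 1e-12)
    }
    # zero weights give identically zero forcing through both paths
    w0 <- dmp_weights(rep(0, 3), kind)
    sc0 <- dmp_as_special_case(w0)
    x <- seq(0.1, 1, length.out = 7)
    expect_equal(as.vector(forcing_synergies(x, 1, sc0$shapes, sc0$coeffs)),
                 rep(0, 7))
    expect_equal(as.vector(forcing_dmp(x, w0, normalize = FALSE)), rep(0, 7))
  }
})
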