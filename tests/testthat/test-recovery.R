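test_that("pattern generation is reproducible and exact at zero noise", {
  shapes <- list(random_shape("discrete", 2, 3, seed = 401))
  co <- task_coefficients("time_varying", matrix(c(1, -0.4), 1, 2))
  grid <- seq(0, 1, length.out = 60)
  p0 <- generate_patterns(shapes, co, grid)
  for (k in 1:2) {
    expect_equal(p0$patterns[, , k],
                 forcing_synergies(grid, k, shapes, co))
  }
  p1 <- generate_patterns(shapes, co, grid, sigma = 0.05, seed = 11)
  p2 <- generate_patterns(shapes, co, grid, sigma = 0.05, seed = 11)
  expect_identical(p1$patterns, p2$patterns)
  # all-zero weights give all-zero patterns before clipping
  co0 <- task_coefficients("time_varying", matrix(0, 1, 2))
  expect_equal(max(abs(generate_patterns(shapes, co0, grid)$patterns)), 0)
  # clipping keeps patterns in [0, 1]
  pc <- generate_patterns(shapes, co, grid, sigma = 0.3, seed = 2,
                          clip = TRUE)
  expect_true(all(pc$patterns >= 0 & pc$patterns <= 1))
})

test_that("zero-noise least-squares recovery of the weights is exact", {
  for (seed in 1:5) {
    set.seed(500 + seed)
    M <- 2; K <- 3; D <- 4
    shapes <- lapply(1:M, function(m) {
      sh <- random_shape("discrete", 2, D, seed = 510 + seed * M + m)
      # unit-max amplitudes: the scale lives in beta (identifiability)
      sh$amplitudes <- sh$amplitudes / max(abs(sh$amplitudes))
      sh
    })
    beta <- matrix(rnorm(M * K, 0, 1.5), M, K)
    co <- task_coefficients("time_varying", beta)
    grid <- seq(0, 1, length.out = 80)
    pats <- generate_patterns(shapes, co, grid)
    rec <- recover_coefficients(pats, shapes)
    expect_lt(max(abs(rec$beta - beta)) / max(abs(beta)), 1e-6)
    expect_lt(max(rec$residual), 1e-10)
  }
})

test_that("per-dimension weights are recovered dimension by dimension", {
  set.seed(77)
  shapes <- lapply(1:2, function(m) random_shape("discrete", 2, 3,
                                                 seed = 540 + m))
  beta <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  co <- task_coefficients("per_dimension", beta)
  grid <- seq(0, 1, length.out = 70)
  pats <- generate_patterns(shapes, co, grid)
  rec <- recover_coefficients(pats, shapes)
  expect_equal(as.array(rec$beta), beta, tolerance = 1e-8)
})

test_that("free time shifts are identified on a grid containing the truth", {
  shapes <- list(random_shape("discrete", 2, 2, seed = 551))
  true_shift <- 0.2
  co <- task_coefficients("time_varying", matrix(1.3, 1, 1),
                          matrix(true_shift, 1, 1), learn_shifts = TRUE)
  grid <- seq(0, 1, length.out = 60)
  pats <- generate_patterns(shapes, co, grid)
  cand <- seq(-0.4, 0.4, by = 0.1)       # coarse grid containing 0.2
  rec <- recover_coefficients(pats, shapes, shift_grid = cand)
  expect_equal(rec$shifts[1, 1], true_shift)
  expect_equal(rec$beta[1, 1], 1.3, tolerance = 1e-8)
  expect_lt(rec$residual[1], 1e-10)
})

test_that("degenerate inputs are handled explicitly", {
  shapes <- list(random_shape("discrete", 2, 2, seed = 561))
  co0 <- task_coefficients("time_varying", matrix(0, 1, 3))
  grid <- seq(0, 1, length.out = 30)
  pats <- generate_patterns(shapes, co0, grid)
  rec <- recover_coefficients(pats, shapes)
  expect_equal(max(abs(rec$beta)), 0)
  # duplicated synergies make the design rank deficient: reported, not hidden
  dup <- list(shapes[[1]], shapes[[1]])
  co2 <- task_coefficients("time_varying", matrix(c(1, 1), 2, 1))
  pats2 <- generate_patterns(dup, co2, grid)
  expect_error(recover_coefficients(pats2, dup), "rank")
})

test_that("recovery error decreases with the pattern noise level", {
  shapes <- list(random_shape("discrete", 2, 3, seed = 571))
  shapes[[1]]$amplitudes <- shapes[[1]]$amplitudes /
    max(abs(shapes[[1]]$amplitudes))
  beta <- matrix(c(1.2, -0.8, 0.5), 1, 3)
  co <- task_coefficients("time_varying", beta)
  grid <- seq(0, 1, length.out = 60)
  mean_err <- vapply(c(0, 0.01, 0.1), function(sg) {
    errs <- vapply(1:20, function(seed) {
      pats <- generate_patterns(shapes, co, grid, sigma = sg, seed = seed)
      rec <- recover_coefficients(pats, shapes)
      sqrt(sum((rec$beta - beta)^2)) / sqrt(sum(beta^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) > 0))
  expect_lt(mean_err[1], 1e-10)
})
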