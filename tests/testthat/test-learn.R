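test_that("single-task objective reduces to the single episode cost", {
  task <- pointmass_task(via_points = 0.15, sigma = 0)
  env <- multitask_env(task)
  lay <- parameter_layout(1, 1, 2, 1, "per_dimension", FALSE, "discrete")
  theta <- runif(lay$total, pmax(lay$lower, -1), pmin(lay$upper, 1))
  dec <- unpack_policy(theta, lay)
  forcing <- function(ph) forcing_synergies(ph, 1, dec$shapes, dec$coeffs)
  desired <- rollout_primitive(env$cfg, forcing)
  direct <- as.numeric(viapoint_cost(pointmass_rollout(task, desired),
                                     task, 1))
  expect_equal(evaluate_multitask(theta, lay, env), direct)
})

test_that("noiseless objective is deterministic; averaging reduces noise variance", {
  task0 <- pointmass_task(sigma = 0)
  env0 <- multitask_env(task0)
  lay <- parameter_layout(5, 1, 2, 1, "per_dimension", FALSE, "discrete")
  theta <- dmpsynergy:::default_policy(lay)
  expect_identical(evaluate_multitask(theta, lay, env0),
                   evaluate_multitask(theta, lay, env0))
  # with motor noise, the mean of 4 rollouts has lower variance than 1
  task <- pointmass_task()
  env <- multitask_env(task)
  set.seed(21)
  one <- replicate(20, evaluate_multitask(theta, lay, env,
                                          seeds = sample.int(1e6, 5)))
  four <- replicate(20, mean(replicate(4,
    evaluate_multitask(theta, lay, env, seeds = sample.int(1e6, 5)))))
  expect_lt(var(four), var(one))
})

test_that("zero budget returns the initial policy unchanged", {
  env <- multitask_env(pointmass_task(sigma = 0))
  fit <- synergy_learn(env, M = 1, N = 2, scheme = "per_dimension",
                       budget = 0, seed = 1)
  expect_equal(fit$par, dmpsynergy:::default_policy(fit$layout))
  expect_equal(fit$evaluations, 0L)
  expect_s3_class(fit, "synergy_fit")
})

test_that("a short search improves on the unforced baseline", {
  task <- pointmass_task(sigma = 0)     # deterministic objective
  env <- multitask_env(task)
  fit <- synergy_learn(env, M = 1, N = 2, scheme = "per_dimension",
                       budget = 400, seed = 2)
  theta0 <- dmpsynergy:::default_policy(fit$layout)
  baseline <- evaluate_multitask(theta0, fit$layout, env)
  expect_lt(fit$value, baseline)
  expect_true(all(diff(fit$curve$best_cost) <= 0))
  # the optimizer never returns something worse than its start
  expect_lte(fit$value, baseline)
})

test_that("frozen-synergy generalization exposes exactly the task-specific block", {
  # reaching scenario: M = 4 synergies, K = 6 tasks, 11 muscles -> 48 free
  shapes <- lapply(1:4, function(m) random_shape("discrete", 1, 11,
                                                 seed = 200 + m))
  task <- arm_task()
  env <- multitask_env(task)
  fit <- generalize_fixed_synergies(shapes, env, scheme = "time_varying",
                                    learn_shifts = TRUE, budget = 0)
  expect_equal(fit$layout$total, 48)
  expect_equal(fit$layout$total,
               count_parameters(6, 4, 1, 11, "time_varying",
                                TRUE)$task_specific)
  expect_true(fit$frozen_shapes)
  expect_identical(fit$shapes, shapes)
  # M = 1, K = 1, weights only: a single free parameter
  t1 <- pointmass_task(via_points = 0.1)
  f1 <- generalize_fixed_synergies(list(random_shape("discrete", 2, 1, 1)),
                                   multitask_env(t1),
                                   scheme = "per_dimension",
                                   learn_shifts = FALSE, budget = 0)
  expect_equal(f1$layout$total, 1)
})

test_that("restricted optimum matches the least-squares oracle on a noiseless recovery objective", {
  # frozen true shapes; objective = squared pattern mismatch, quadratic in
  # beta, so CMA must find the least-squares solution
  set.seed(31)
  shapes <- list(random_shape("discrete", 2, 2, seed = 301))
  truth <- task_coefficients("time_varying", matrix(c(0.8, -0.5), 1, 2))
  grid <- seq(0, 1, length.out = 40)
  pats <- generate_patterns(shapes, truth, grid)
  lay <- parameter_layout(2, 1, 2, 2, "time_varying", FALSE, "discrete",
                          free_shapes = FALSE)
  obj <- function(theta) {
    dec <- unpack_policy(theta, lay, shapes = shapes)
    sum(vapply(1:2, function(k)
      sum((forcing_synergies(grid, k, shapes, dec$coeffs) -
             pats$patterns[, , k])^2), numeric(1)))
  }
  opt <- cma_es(obj, numeric(2), 0.5, budget = 1500, seed = 5)
  ls_fit <- recover_coefficients(pats, shapes)
  expect_equal(opt$par, as.vector(ls_fit$beta), tolerance = 1e-3)
  expect_equal(opt$par, c(0.8, -0.5), tolerance = 1e-3)
})

test_that("fit methods expose coefficients, predictions and simulations coherently", {
  env <- multitask_env(pointmass_task(sigma = 0))
  fit <- synergy_learn(env, M = 1, N = 2, scheme = "per_dimension",
                       budget = 150, seed = 3)
  cf <- coef(fit)
  expect_named(cf, c("beta", "shifts", "shapes"))
  expect_equal(dim(cf$beta), c(1, 5, 1))
  pr <- predict(fit, tasks = 2)
  expect_s3_class(pr$task_2, "primitive_rollout")
  sims <- simulate(fit, nsim = 2, seed = 7)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]][[1]], "episode_result")
  # noiseless environment: simulation reproduces prediction tracking
  out <- utils::capture.output(print(fit))
  expect_true(any(grepl("synergy_fit", out)))
  out2 <- utils::capture.output(print(summary(fit)))
  expect_true(any(grepl("beta", out2)))
})
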