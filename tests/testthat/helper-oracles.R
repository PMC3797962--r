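# Independent numerical oracles used across tests.

# matrix exponential by scaling and squaring of the Taylor series
# (solve-free, handles defective matrices)
expm_series <- function(A) {
  n <- nrow(A)
  s <- max(0, ceiling(log2(max(1, norm(A, "1")))))
  As <- A / 2^s
  E <- diag(n); term <- diag(n)
  for (k in 1:30) {
    term <- term %*% As / k
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

# closed-form solution of the unforced attractor (one DoF):
# x = (y, z), xdot = A x + b, evaluated at times t
attractor_closed_form <- function(cfg, times, y0 = 0, z0 = 0) {
  A <- matrix(c(0, 1 / cfg$tau,
                -cfg$alpha_z * cfg$beta_z / cfg$tau, -cfg$alpha_z / cfg$tau),
              2, 2, byrow = TRUE)
  xstar <- c(cfg$g[1], 0)
  x0 <- c(y0, z0) - xstar
  t(vapply(times, function(t) expm_series(A * t) %*% x0 + xstar, numeric(2)))
}

# brute-force synergy evaluation straight from the kernel formulas
naive_synergy <- function(x, shape, d, shift) {
  val <- 0
  for (n in seq_len(shape$N)) {
    a <- shape$amplitudes[n, d]; mu <- shape$means[n, d]
    h <- shape$bandwidths[n, d]
    val <- val + if (shape$kind == "discrete") {
      a * exp(-(x - mu + shift)^2 / (2 * h^2))
    } else {
      a * exp(h * (cos(x - mu + shift) - 1))
    }
  }
  val
}

# random synergy shape generator for property tests
random_shape <- function(kind, N, D, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hi <- if (kind == "discrete") 1 else 2 * pi
  synergy_shape(kind,
                amplitudes = matrix(stats::runif(N * D, -2, 2), N, D),
                means = matrix(stats::runif(N * D, 0, hi), N, D),
                bandwidths = matrix(stats::runif(N * D, 0.05, 1.5), N, D))
}

# planar forward kinematics of the walker CoMs from a coefficient matrix;
# positions only, used to finite-difference velocities in impact tests
walker_com_positions <- function(theta, task, origin = c(0, 0)) {
  e <- cbind(cos(theta), sin(theta))
  t(apply(task$Cm, 1, function(cc) origin + colSums(cc * e)))
}
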