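#' Primitive configuration
#'
#' Bundles the constants of one movement primitive: the damped-spring
#' attractor rates, the temporal scaling, the goal state, the phase law and
#' the integration grid.  The attractor per actuator dimension is
#' \deqn{\tau \dot z = \alpha_z(\beta_z(g - y^*) - z) + f, \quad
#'       \tau \dot y^* = z,}
#' driven by a forcing function f of the phase.  The phase abstracts time:
#' discrete movements use \eqn{\tau \dot s = -\alpha_s s} (s decays from 1
#' toward 0, switching the forcing off), rhythmic movements use
#' \eqn{\tau \dot\phi = 1} (phi advances linearly and wraps).
#'
#' @param kind `"discrete"` or `"rhythmic"`.
#' @param alpha_z,beta_z Attractor rate constants (> 0).  `beta_z` close to
#'   `alpha_z / 4` gives near-critical damping.
#' @param tau Temporal scaling factor in seconds (> 0); larger `tau` slows
#'   the movement down.
#' @param g Goal state, one value per actuator dimension.
#' @param dt Integration step in seconds.
#' @param T Number of time steps in a rollout.
#' @param alpha_s Discrete-phase decay rate.  Default `NULL` picks
#'   `tau * log(100) / (T * dt)` so that the phase has decayed to 0.01 at
#'   the movement end, a conventional choice when no value is prescribed.
#' @param y0,z0 Initial desired position / internal state per dimension
#'   (defaults: 0).
#' @return An object of class `"primitive_config"`.
#' @export
primitive_config <- function(kind = c("discrete", "rhythmic"),
                             alpha_z = 2, beta_z = 0.9, tau = 0.1,
                             g = 0, dt = 0.01, T = 50L,
                             alpha_s = NULL, y0 = NULL, z0 = NULL) {
  kind <- match.arg(kind)
  stopifnot(alpha_z > 0, beta_z > 0, tau > 0, dt > 0, T >= 1)
  if (is.null(alpha_s)) alpha_s <- tau * log(100) / (T * dt)
  stopifnot(alpha_s > 0)
  D <- length(g)
  if (is.null(y0)) y0 <- rep(0, D)
  if (is.null(z0)) z0 <- rep(0, D)
  stopifnot(length(y0) == D, length(z0) == D)
  structure(
    list(kind = kind, alpha_z = alpha_z, beta_z = beta_z, tau = tau,
         g = g, dt = dt, T = as.integer(T), alpha_s = alpha_s,
         y0 = y0, z0 = z0, D = D),
    class = "primitive_config")
}

#' @export
print.primitive_config <- function(x, ...) {
  cat(sprintf(
    "<primitive_config> %s | D = %d | alpha_z = %g beta_z = %g tau = %g | dt = %g T = %d\n",
    x$kind, x$D, x$alpha_z, x$beta_z, x$tau, x$dt, x$T))
  invisible(x)
}

#' Advance the phase variable one step
#'
#' Explicit Euler step of the phase law: discrete
#' `s <- s + dt * (-alpha_s * s / tau)`, rhythmic `phi <- phi + dt / tau`.
#'
#' @param phase Current phase value.
#' @param cfg A [primitive_config()].
#' @return The phase after one step of `cfg$dt`.
#' @export
step_phase <- function(phase, cfg) {
  if (cfg$kind == "discrete") {
    phase * (1 - cfg$dt * cfg$alpha_s / cfg$tau)
  } else {
    phase + cfg$dt / cfg$tau
  }
}

#' Full phase trace for a rollout
#'
#' Returns the T phase values visited by repeated [step_phase()] calls,
#' starting at s = 1 (discrete) or phi = `phi0` (rhythmic).
#'
#' @param cfg A [primitive_config()].
#' @param phi0 Starting angle for rhythmic primitives (default 0).
#' @return Numeric vector of length `cfg$T`.
#' @export
phase_trace <- function(cfg, phi0 = 0) {
  t <- seq_len(cfg$T) - 1L
  if (cfg$kind == "discrete") {
    (1 - cfg$dt * cfg$alpha_s / cfg$tau)^t
  } else {
    phi0 + t * cfg$dt / cfg$tau
  }
}

#' Fixed basis grid for classical movement primitives
#'
#' Means equally spaced on [0, 1] (discrete) or [0, 2pi) (rhythmic);
#' bandwidths set so neighbouring kernels overlap at half height.
#'
#' @param N Number of basis functions.
#' @param kind `"discrete"` or `"rhythmic"`.
#' @return List with `means` and `bandwidths`, length N each.
#' @export
dmp_grid <- function(N, kind = c("discrete", "rhythmic")) {
  kind <- match.arg(kind)
  if (kind == "discrete") {
    means <- if (N == 1L) 0.5 else seq(0, 1, length.out = N)
    spacing <- if (N == 1L) 0.5 else means[2] - means[1]
    h <- spacing / (2 * sqrt(2 * log(2)))     # 50% overlap at midpoints
    list(means = means, bandwidths = rep(h, N))
  } else {
    means <- 2 * pi * (seq_len(N) - 1L) / N
    spacing <- 2 * pi / N
    h <- log(2) / (1 - cos(spacing / 2))      # 50% overlap at midpoints
    list(means = means, bandwidths = rep(h, N))
  }
}

#' Classical movement-primitive weights on a fixed grid
#'
#' @param w Weight vector (D = 1) or N x D matrix of weights.
#' @param kind `"discrete"` or `"rhythmic"`.
#' @param grid Optional list with `means` and `bandwidths`; default
#'   [dmp_grid()] for the given N.
#' @return An object of class `"dmp_weights"`.
#' @export
dmp_weights <- function(w, kind = c("discrete", "rhythmic"), grid = NULL) {
  kind <- match.arg(kind)
  w <- as.matrix(w)
  N <- nrow(w)
  if (is.null(grid)) grid <- dmp_grid(N, kind)
  stopifnot(length(grid$means) == N, length(grid$bandwidths) == N)
  structure(list(w = w, kind = kind, means = grid$means,
                 bandwidths = grid$bandwidths, N = N, D = ncol(w)),
            class = "dmp_weights")
}

#' Classical movement-primitive forcing function
#'
#' Normalized weighted basis mixture: discrete
#' \eqn{f(s) = \sum_n \Psi_n(s) w_n s / \sum_n \Psi_n(s)}, rhythmic the same
#' without the trailing phase factor.  With `normalize = FALSE` the
#' normalizer is dropped (the form under which the synergy representation
#' reproduces classical primitives exactly, see [dmp_as_special_case()]).
#'
#' @param x Phase value(s).
#' @param weights A [dmp_weights()] object.
#' @param normalize Divide by the summed basis activations (default TRUE).
#' @return `length(x)` x D matrix of forcing values.
#' @export
forcing_dmp <- function(x, weights, normalize = TRUE) {
  stopifnot(inherits(weights, "dmp_weights"))
  kern <- if (weights$kind == "discrete") {
    function(x, n) exp(-((x - weights$means[n])^2) /
                         (2 * weights$bandwidths[n]^2))
  } else {
    function(x, n) exp(weights$bandwidths[n] *
                         (cos(x - weights$means[n]) - 1))
  }
  Psi <- vapply(seq_len(weights$N), function(n) kern(x, n),
                numeric(length(x)))
  Psi <- matrix(Psi, nrow = length(x))
  num <- Psi %*% weights$w                      # length(x) x D
  if (normalize) {
    norm <- rowSums(Psi)
    if (any(norm < .Machine$double.eps)) {
      stop("vanishing basis normalizer at the evaluated phase")
    }
    num <- num / norm
  }
  if (weights$kind == "discrete") num <- num * x
  num
}

#' Task-specific synergy combination coefficients
#'
#' Holds the mixing weights beta and the time shifts for each of K tasks
#' under one of three coefficient-sharing schemes:
#' \describe{
#'   \item{per_dimension}{beta and shifts indexed (synergy m, task k,
#'     dimension d); the most general scheme (Hadamard-product mixing).}
#'   \item{time_varying}{scalar beta and a single shift per (m, k), shared
#'     across all dimensions: the synergy is scaled and shifted in time as a
#'     whole, the classical time-varying muscle-synergy semantics.}
#'   \item{dmp_special_case}{fixed beta = 1, shifts = 0, M = 1; classical
#'     movement primitives expressed in the synergy representation.}
#' }
#'
#' @param scheme Coefficient-sharing scheme.
#' @param beta Mixing weights: M x K matrix (`time_varying`,
#'   `dmp_special_case`) or M x K x D array (`per_dimension`).
#' @param shifts Time shifts, same shape as `beta`; default all zero.
#' @param learn_shifts Logical flag: are the shifts free parameters?  When
#'   FALSE all shifts must be (and remain) zero.
#' @return An object of class `"task_coefficients"`.
#' @export
task_coefficients <- function(scheme = c("per_dimension", "time_varying",
                                         "dmp_special_case"),
                              beta, shifts = NULL, learn_shifts = TRUE) {
  scheme <- match.arg(scheme)
  if (scheme == "per_dimension") {
    beta <- as.array(beta)
    if (length(dim(beta)) != 3L) stop("per_dimension beta must be an M x K x D array")
  } else {
    beta <- as.matrix(beta)
  }
  if (is.null(shifts)) {
    shifts <- beta * 0
    learn_shifts <- FALSE
  }
  if (!all(dim(as.array(shifts)) == dim(as.array(beta)))) {
    stop("`shifts` must have the same shape as `beta`")
  }
  if (!learn_shifts && any(shifts != 0)) {
    stop("with learn_shifts = FALSE all shifts must be zero")
  }
  dims <- dim(as.array(beta))
  structure(
    list(scheme = scheme, beta = beta, shifts = shifts,
         learn_shifts = isTRUE(learn_shifts),
         M = dims[1], K = dims[2],
         D = if (scheme == "per_dimension") dims[3] else NA_integer_),
    class = "task_coefficients")
}

#' Synergy-based forcing function
#'
#' The forcing for task k is a weighted superposition of the M shared
#' synergies, each scaled by its task-specific weight and shifted by its
#' task-specific phase shift:
#' discrete \eqn{f(s,k,d) = \sum_m \beta_{m,k[,d]}
#' \Lambda(s, \theta_{m,d}, \Delta s_{m,k[,d]})\, s}, rhythmic the same with
#' \eqn{\Omega} and no trailing phase factor.  Under the `time_varying`
#' scheme beta and the shift are scalars shared by all dimensions.
#'
#' @param x Phase value(s).
#' @param k Task index (1..K).
#' @param shapes List of M [synergy_shape()] objects (same kind, N, D).
#' @param coeffs A [task_coefficients()] object.
#' @param d Optional single dimension index; default returns all dimensions.
#' @return `length(x)` x D matrix (or vector when `d` is given).
#' @export
forcing_synergies <- function(x, k, shapes, coeffs, d = NULL) {
  stopifnot(inherits(coeffs, "task_coefficients"))
  if (inherits(shapes, "synergy_shape")) shapes <- list(shapes)
  M <- length(shapes)
  if (M != coeffs$M) stop("number of shapes does not match coefficients")
  if (k < 1 || k > coeffs$K) stop("task index out of range")
  kind <- shapes[[1]]$kind
  D <- shapes[[1]]$D
  for (sh in shapes) {
    if (sh$kind != kind || sh$D != D || sh$N != shapes[[1]]$N) {
      stop("all synergy shapes must share kind, N and D")
    }
  }
  if (coeffs$scheme == "per_dimension" && !is.na(coeffs$D) && coeffs$D != D) {
    stop("coefficient dimension D does not match shapes")
  }
  out <- matrix(0, length(x), D)
  for (m in seq_len(M)) {
    if (coeffs$scheme == "per_dimension") {
      b <- coeffs$beta[m, k, ]
      sft <- coeffs$shifts[m, k, ]
    } else {
      b <- rep(coeffs$beta[m, k], D)
      sft <- rep(coeffs$shifts[m, k], D)
    }
    W <- eval_synergy_matrix(x, shapes[[m]], sft)
    out <- out + W * rep(b, each = length(x))
  }
  if (kind == "discrete") out <- out * x
  if (!is.null(d)) {
    if (d < 1 || d > D) stop("dimension index out of range")
    out <- out[, d]
  }
  out
}

#' One explicit-Euler step of the attractor system
#'
#' Per dimension: `z <- z + dt * (alpha_z * (beta_z * (g - y) - z) + f) / tau`
#' then `y <- y + dt * z / tau`.  The desired velocity is `z / tau`.
#'
#' @param state List with numeric vectors `y` and `z` (length D).
#' @param f Forcing value per dimension.
#' @param cfg A [primitive_config()].
#' @return Updated state list with elements `y`, `z`, `yd` (= z / tau).
#' @export
step_attractor <- function(state, f, cfg) {
  z <- state$z + cfg$dt *
    (cfg$alpha_z * (cfg$beta_z * (cfg$g - state$y) - state$z) + f) / cfg$tau
  y <- state$y + cfg$dt * state$z / cfg$tau
  list(y = y, z = z, yd = z / cfg$tau)
}

# one RK4 step of the attractor with forcing held constant (zero-order hold)
rk4_attractor <- function(state, f, cfg) {
  deriv <- function(y, z) {
    list(dy = z / cfg$tau,
         dz = (cfg$alpha_z * (cfg$beta_z * (cfg$g - y) - z) + f) / cfg$tau)
  }
  h <- cfg$dt
  k1 <- deriv(state$y, state$z)
  k2 <- deriv(state$y + h / 2 * k1$dy, state$z + h / 2 * k1$dz)
  k3 <- deriv(state$y + h / 2 * k2$dy, state$z + h / 2 * k2$dz)
  k4 <- deriv(state$y + h * k3$dy, state$z + h * k3$dz)
  y <- state$y + h / 6 * (k1$dy + 2 * k2$dy + 2 * k3$dy + k4$dy)
  z <- state$z + h / 6 * (k1$dz + 2 * k2$dz + 2 * k3$dz + k4$dz)
  list(y = y, z = z, yd = z / cfg$tau)
}

#' Integrate a movement primitive into a desired trajectory
#'
#' Rolls the attractor system forward for T steps, advancing the phase once
#' per step and applying the forcing.  Deterministic given its inputs.
#'
#' @param cfg A [primitive_config()].
#' @param forcing Either `NULL` (unforced), a T x D matrix of precomputed
#'   forcing values, or a function `function(phase)` returning a
#'   `length(phase)` x D matrix (evaluated once on the whole phase trace).
#' @param method `"euler"` (default; matches the per-step environment
#'   integration) or `"rk4"` (higher-order, for accuracy studies).
#' @param phi0 Starting angle for rhythmic primitives.
#' @return An object of class `"primitive_rollout"`: list with `time`
#'   (length T), `phase`, `y` and `yd` (T x D matrices), `cfg`.
#' @export
rollout_primitive <- function(cfg, forcing = NULL, method = c("euler", "rk4"),
                              phi0 = 0) {
  method <- match.arg(method)
  ph <- phase_trace(cfg, phi0)
  D <- cfg$D
  f <- if (is.null(forcing)) {
    matrix(0, cfg$T, D)
  } else if (is.function(forcing)) {
    fm <- forcing(ph)
    matrix(fm, nrow = cfg$T, ncol = D)
  } else {
    stopifnot(nrow(forcing) == cfg$T, ncol(forcing) == D)
    forcing
  }
  y <- matrix(NA_real_, cfg$T, D)
  yd <- matrix(NA_real_, cfg$T, D)
  state <- list(y = cfg$y0, z = cfg$z0, yd = cfg$z0 / cfg$tau)
  stepper <- if (method == "euler") step_attractor else rk4_attractor
  for (t in seq_len(cfg$T)) {
    y[t, ] <- state$y
    yd[t, ] <- state$yd
    if (t < cfg$T) state <- stepper(state, f[t, ], cfg)
  }
  structure(
    list(time = (seq_len(cfg$T) - 1L) * cfg$dt, phase = ph,
         y = y, yd = yd, forcing = f, cfg = cfg),
    class = "primitive_rollout")
}

#' @export
print.primitive_rollout <- function(x, ...) {
  cat(sprintf("<primitive_rollout> %s | T = %d, D = %d | final y* = %s\n",
              x$cfg$kind, x$cfg$T, x$cfg$D,
              paste(signif(x$y[nrow(x$y), ], 4), collapse = ", ")))
  invisible(x)
}

#' Express classical movement primitives in the synergy representation
#'
#' A classical primitive with weights w_n on a fixed grid equals a single
#' synergy (M = 1) whose kernel amplitudes are the weights and whose means
#' and bandwidths are copied from the grid, combined with beta = 1 and zero
#' shift -- provided the classical forcing is taken unnormalized (the
#' synergy superposition carries no normalizer).
#'
#' @param weights A [dmp_weights()] object.
#' @return List with `shapes` (list of one [synergy_shape()]) and `coeffs`
#'   (a [task_coefficients()] with scheme `"dmp_special_case"`), such that
#'   `forcing_synergies(x, 1, shapes, coeffs)` equals
#'   `forcing_dmp(x, weights, normalize = FALSE)` at every phase.
#' @export
dmp_as_special_case <- function(weights) {
  stopifnot(inherits(weights, "dmp_weights"))
  shape <- synergy_shape(
    kind = weights$kind,
    amplitudes = weights$w,
    means = matrix(weights$means, weights$N, weights$D),
    bandwidths = matrix(weights$bandwidths, weights$N, weights$D))
  coeffs <- task_coefficients("dmp_special_case",
                              beta = matrix(1, 1, 1),
                              learn_shifts = FALSE)
  list(shapes = list(shape), coeffs = coeffs)
}
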