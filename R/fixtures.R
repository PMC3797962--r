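#' Generate synthetic excitation patterns with known ground truth
#'
#' Evaluates the synergy forcing on a phase grid for every task and
#' dimension, adds i.i.d. Gaussian noise, and optionally clips to [0, 1]
#' (the excitation range).  The result emulates the statistical structure
#' of multi-muscle excitation patterns generated from shared time-varying
#' synergies, and serves as ground truth for recovery tests.
#'
#' @param shapes List of M [synergy_shape()]s (the ground-truth synergies).
#' @param coeffs Ground-truth [task_coefficients()].
#' @param grid Phase grid on which patterns are generated.
#' @param sigma Noise standard deviation (default 0).
#' @param seed Optional integer seed.
#' @param clip Clip the noisy patterns to [0, 1]?  Default FALSE.
#' @return An object of class `"synthetic_patterns"`: list with `patterns`
#'   (grid x D x K array), `grid`, `shapes`, `coeffs`, `sigma`, `seed`,
#'   `clip`.
#' @export
generate_patterns <- function(shapes, coeffs, grid, sigma = 0, seed = NULL,
                              clip = FALSE) {
  if (inherits(shapes, "synergy_shape")) shapes <- list(shapes)
  stopifnot(inherits(coeffs, "task_coefficients"))
  if (!is.null(seed)) set.seed(seed)
  D <- shapes[[1]]$D; K <- coeffs$K
  pat <- array(NA_real_, dim = c(length(grid), D, K))
  for (k in seq_len(K)) {
    f <- forcing_synergies(grid, k, shapes, coeffs)
    if (sigma > 0) f <- f + matrix(stats::rnorm(length(f), 0, sigma),
                                   nrow(f), ncol(f))
    if (clip) f <- pmin(pmax(f, 0), 1)
    pat[, , k] <- f
  }
  structure(list(patterns = pat, grid = grid, shapes = shapes,
                 coeffs = coeffs, sigma = sigma, seed = seed, clip = clip),
            class = "synthetic_patterns")
}

#' @export
print.synthetic_patterns <- function(x, ...) {
  d <- dim(x$patterns)
  cat(sprintf(
    "<synthetic_patterns> %d grid points x %d dimension(s) x %d task(s), sigma = %g\n",
    d[1], d[2], d[3], x$sigma))
  invisible(x)
}

# design matrix for one task: column m is the forcing of synergy m alone
# (beta = 1) at candidate shift, stacked over grid and dimensions
recovery_design <- function(grid, shapes, scheme, shifts_mk, d = NULL) {
  M <- length(shapes)
  cols <- lapply(seq_len(M), function(m) {
    cf <- task_coefficients(
      if (scheme == "per_dimension") "per_dimension" else "time_varying",
      beta = if (scheme == "per_dimension")
        array(1, dim = c(1, 1, shapes[[m]]$D)) else matrix(1, 1, 1),
      shifts = if (scheme == "per_dimension")
        array(shifts_mk[m], dim = c(1, 1, shapes[[m]]$D)) else
          matrix(shifts_mk[m], 1, 1),
      learn_shifts = TRUE)
    f <- forcing_synergies(grid, 1, shapes[m], cf)
    if (is.null(d)) as.vector(f) else f[, d]
  })
  do.call(cbind, cols)
}

#' Recover combination coefficients from excitation patterns
#'
#' Inverse problem for the synergy superposition: given the synergy shapes,
#' the forcing is linear in the mixing weights beta, so with known (fixed)
#' time shifts the weights are recovered per task by closed-form least
#' squares.  With `shift_grid` supplied, a grid search over per-task shift
#' combinations with inner least squares finds both shifts and weights.
#' Rank deficiency of the design matrix is reported as an error, not
#' silently regularized.
#'
#' @param patterns A [generate_patterns()] result, or a grid x D x K array
#'   with the phase grid passed via `grid`.
#' @param shapes Known synergy shapes (list of M).
#' @param shifts Fixed time shifts (M x K matrix or scalar, default 0);
#'   ignored when `shift_grid` is given.
#' @param shift_grid Optional vector of candidate shifts; triggers the
#'   grid search (all `length(shift_grid)^M` combinations per task).
#' @param grid Phase grid when `patterns` is a raw array.
#' @return An object of class `"synergy_recovery"`: `beta` (M x K or
#'   M x K x D), `shifts` (M x K), `residual` (per task RMS), `scheme`.
#' @export
recover_coefficients <- function(patterns, shapes, shifts = 0,
                                 shift_grid = NULL, grid = NULL) {
  if (inherits(patterns, "synthetic_patterns")) {
    grid <- patterns$grid
    scheme <- patterns$coeffs$scheme
    pat <- patterns$patterns
  } else {
    pat <- patterns
    scheme <- "time_varying"
    if (is.null(grid)) stop("`grid` is required for raw pattern arrays")
  }
  if (inherits(shapes, "synergy_shape")) shapes <- list(shapes)
  M <- length(shapes); D <- shapes[[1]]$D; K <- dim(pat)[3]
  if (dim(pat)[2] != D) stop("pattern dimensions do not match shapes")
  if (scheme == "dmp_special_case") scheme <- "time_varying"
  shifts_fix <- if (is.matrix(shifts)) shifts else matrix(shifts, M, K)

  per_dim <- scheme == "per_dimension"
  beta <- if (per_dim) array(NA_real_, dim = c(M, K, D)) else
    matrix(NA_real_, M, K)
  shifts_hat <- matrix(0, M, K)
  residual <- numeric(K)

  solve_ls <- function(X, y) {
    qr_X <- qr(X)
    if (qr_X$rank < ncol(X)) {
      stop("rank-deficient recovery design (collinear synergies)")
    }
    qr.coef(qr_X, y)
  }

  for (k in seq_len(K)) {
    y_all <- as.vector(pat[, , k])
    fit_at <- function(sft) {
      if (per_dim) {
        bhat <- matrix(NA_real_, M, D)
        resid2 <- 0
        for (d in seq_len(D)) {
          X <- recovery_design(grid, shapes, scheme, sft, d = d)
          yv <- pat[, d, k]
          bd <- solve_ls(X, yv)
          bhat[, d] <- bd
          resid2 <- resid2 + sum((yv - X %*% bd)^2)
        }
        list(beta = bhat, rss = resid2)
      } else {
        X <- recovery_design(grid, shapes, scheme, sft)
        bhat <- solve_ls(X, y_all)
        list(beta = bhat, rss = sum((y_all - X %*% bhat)^2))
      }
    }
    if (is.null(shift_grid)) {
      ft <- fit_at(shifts_fix[, k])
      shifts_hat[, k] <- shifts_fix[, k]
    } else {
      combos <- as.matrix(expand.grid(rep(list(shift_grid), M)))
      best <- NULL
      for (i in seq_len(nrow(combos))) {
        cand <- tryCatch(fit_at(combos[i, ]), error = function(e) NULL)
        if (!is.null(cand) && (is.null(best) || cand$rss < best$rss)) {
          best <- cand; shifts_hat[, k] <- combos[i, ]
        }
      }
      if (is.null(best)) stop("no admissible shift combination found")
      ft <- best
    }
    if (per_dim) beta[, k, ] <- ft$beta else beta[, k] <- ft$beta
    residual[k] <- sqrt(ft$rss / length(y_all))
  }
  structure(list(beta = beta, shifts = shifts_hat, residual = residual,
                 scheme = scheme),
            class = "synergy_recovery")
}

#' @export
print.synergy_recovery <- function(x, ...) {
  cat(sprintf("<synergy_recovery> %s | %d synergies x %d tasks | RMS residual %s\n",
              x$scheme, dim(as.array(x$beta))[1], dim(as.array(x$beta))[2],
              paste(signif(x$residual, 3), collapse = ", ")))
  invisible(x)
}
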