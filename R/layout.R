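#' Count free policy parameters
#'
#' In multi-task learning a single flat policy vector encodes all
#' task-specific combination parameters (mixing weights beta and, when
#' learned, time shifts) together with the shared synergy parameters
#' (amplitude, mean and bandwidth for each of the N kernels in each of the
#' D dimensions of each of the M synergies).
#'
#' Task-specific count: `K * M * (1 + learn_shifts)` under the
#' `time_varying` scheme (scalar weight and shift per task and synergy), or
#' `K * M * D * (1 + learn_shifts)` under `per_dimension`.  Shared count:
#' `3 * N * D * M`.
#'
#' @param K Number of tasks.
#' @param M Number of shared synergies.
#' @param N Kernels per synergy per dimension.
#' @param D Actuator dimensions.
#' @param scheme `"time_varying"` or `"per_dimension"`.
#' @param learn_shifts Logical or 0/1: are time shifts free parameters?
#' @return Named list with `task_specific`, `shared`, `total`.
#' @examples
#' # one shared synergy of two kernels, five tasks, weights only:
#' count_parameters(K = 5, M = 1, N = 2, D = 1,
#'                  scheme = "per_dimension", learn_shifts = FALSE)$total  # 11
#' @export
count_parameters <- function(K, M, N, D,
                             scheme = c("time_varying", "per_dimension"),
                             learn_shifts = TRUE) {
  scheme <- match.arg(scheme)
  stopifnot(K >= 1, M >= 1, N >= 1, D >= 1)
  ls <- as.integer(as.logical(learn_shifts))
  task_specific <- if (scheme == "time_varying") {
    K * M * (1L + ls)
  } else {
    K * M * D * (1L + ls)
  }
  shared <- 3L * N * D * M
  list(task_specific = task_specific, shared = shared,
       total = task_specific + shared)
}

#' Describe the flat policy vector layout
#'
#' A bijection between the flat vector used by the optimizer and the
#' semantic parameters.  Block order: all beta, then all shifts (when
#' learned), then per synergy m the shape block `[a, mu, log h]` for each
#' kernel n within each dimension d.  Bandwidths are log-parametrized in
#' the flat vector so that any real value maps to a positive bandwidth.
#'
#' @inheritParams count_parameters
#' @param kind Basis kind, `"discrete"` or `"rhythmic"`; sets the default
#'   bound boxes for means and shifts.
#' @param free_shapes If FALSE the shared shape block is excluded (frozen
#'   synergies; only task-specific parameters are optimized).
#' @return An object of class `"parameter_layout"` with counts, index
#'   blocks, and per-coordinate `lower` / `upper` bound vectors.
#' @export
parameter_layout <- function(K, M, N, D,
                             scheme = c("time_varying", "per_dimension"),
                             learn_shifts = TRUE,
                             kind = c("discrete", "rhythmic"),
                             free_shapes = TRUE) {
  scheme <- match.arg(scheme)
  kind <- match.arg(kind)
  cnt <- count_parameters(K, M, N, D, scheme, learn_shifts)
  n_beta <- if (scheme == "time_varying") M * K else M * K * D
  n_shift <- if (isTRUE(as.logical(learn_shifts))) n_beta else 0L
  n_shape <- if (free_shapes) 3L * N * D * M else 0L
  total <- n_beta + n_shift + n_shape
  idx_beta <- seq_len(n_beta)
  idx_shift <- if (n_shift > 0) n_beta + seq_len(n_shift) else integer(0)
  idx_shape <- if (n_shape > 0) n_beta + n_shift + seq_len(n_shape) else integer(0)

  phase_hi <- if (kind == "discrete") 1 else 2 * pi
  shift_hi <- if (kind == "discrete") 1 else 2 * pi
  lower <- numeric(total); upper <- numeric(total)
  lower[idx_beta] <- -100; upper[idx_beta] <- 100
  if (n_shift > 0) { lower[idx_shift] <- -shift_hi; upper[idx_shift] <- shift_hi }
  if (n_shape > 0) {
    # within each kernel triple: a, mu, log h
    trip <- matrix(idx_shape, nrow = 3L)
    lower[trip[1, ]] <- -100;        upper[trip[1, ]] <- 100
    lower[trip[2, ]] <- 0;           upper[trip[2, ]] <- phase_hi
    lower[trip[3, ]] <- log(1e-3);   upper[trip[3, ]] <- log(10)
  }
  structure(
    list(K = K, M = M, N = N, D = D, scheme = scheme,
         learn_shifts = isTRUE(as.logical(learn_shifts)), kind = kind,
         free_shapes = isTRUE(free_shapes),
         counts = cnt, total = total,
         idx_beta = idx_beta, idx_shift = idx_shift, idx_shape = idx_shape,
         lower = lower, upper = upper),
    class = "parameter_layout")
}

#' @export
print.parameter_layout <- function(x, ...) {
  cat(sprintf(
    "<parameter_layout> K=%d M=%d N=%d D=%d %s shifts=%s | task-specific %d + shared %d = %d (flat length %d)\n",
    x$K, x$M, x$N, x$D, x$scheme, x$learn_shifts,
    x$counts$task_specific, x$counts$shared, x$counts$total, x$total))
  invisible(x)
}

#' Flatten coefficients and shapes into a policy vector
#'
#' Inverse of [unpack_policy()]; `unpack_policy(pack_policy(...))` is the
#' identity.  Beta and shift blocks are flattened in R's column-major array
#' order; the shape block is ordered synergy-major, then dimension, then
#' kernel, with `[a, mu, log h]` per kernel.
#'
#' @param coeffs A [task_coefficients()] object.
#' @param shapes List of M [synergy_shape()] objects (ignored when the
#'   layout has `free_shapes = FALSE`).
#' @param layout A [parameter_layout()].
#' @return Numeric vector of length `layout$total`.
#' @export
pack_policy <- function(coeffs, shapes, layout) {
  stopifnot(inherits(layout, "parameter_layout"))
  theta <- numeric(layout$total)
  theta[layout$idx_beta] <- as.vector(coeffs$beta)
  if (length(layout$idx_shift) > 0) {
    theta[layout$idx_shift] <- as.vector(coeffs$shifts)
  }
  if (layout$free_shapes) {
    if (inherits(shapes, "synergy_shape")) shapes <- list(shapes)
    block <- unlist(lapply(shapes, function(sh) {
      v <- numeric(0)
      for (d in seq_len(sh$D)) for (n in seq_len(sh$N)) {
        v <- c(v, sh$amplitudes[n, d], sh$means[n, d], log(sh$bandwidths[n, d]))
      }
      v
    }))
    theta[layout$idx_shape] <- block
  }
  theta
}

#' Rebuild coefficients and shapes from a flat policy vector
#'
#' @param theta Numeric vector of length `layout$total`.
#' @param layout A [parameter_layout()].
#' @param shapes Fixed shapes to reuse when `layout$free_shapes` is FALSE.
#' @return List with `coeffs` ([task_coefficients()]) and `shapes` (list of
#'   M [synergy_shape()]).
#' @export
unpack_policy <- function(theta, layout, shapes = NULL) {
  stopifnot(inherits(layout, "parameter_layout"))
  if (length(theta) != layout$total) {
    stop(sprintf("policy vector has length %d, layout expects %d",
                 length(theta), layout$total))
  }
  K <- layout$K; M <- layout$M; N <- layout$N; D <- layout$D
  bdim <- if (layout$scheme == "per_dimension") c(M, K, D) else c(M, K)
  beta <- array(theta[layout$idx_beta], dim = bdim)
  shifts <- if (length(layout$idx_shift) > 0) {
    array(theta[layout$idx_shift], dim = bdim)
  } else NULL
  if (layout$scheme != "per_dimension") {
    beta <- as.matrix(array(beta, dim = c(M, K)))
    if (!is.null(shifts)) shifts <- as.matrix(array(shifts, dim = c(M, K)))
  }
  coeffs <- task_coefficients(layout$scheme, beta, shifts,
                              learn_shifts = layout$learn_shifts)
  if (layout$free_shapes) {
    vals <- theta[layout$idx_shape]
    per_syn <- 3L * N * D
    shapes <- vector("list", M)
    for (m in seq_len(M)) {
      v <- vals[(m - 1L) * per_syn + seq_len(per_syn)]
      trip <- matrix(v, nrow = 3L)          # columns: kernel within dimension
      a <- matrix(trip[1, ], N, D)
      mu <- matrix(trip[2, ], N, D)
      h <- matrix(exp(trip[3, ]), N, D)
      shapes[[m]] <- synergy_shape(layout$kind, a, mu, h)
    }
  } else {
    if (is.null(shapes)) stop("frozen-shape layout needs `shapes` to rebuild")
    if (inherits(shapes, "synergy_shape")) shapes <- list(shapes)
  }
  list(coeffs = coeffs, shapes = shapes)
}
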