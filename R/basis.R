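#' Parametrized basis functions and synergies
#'
#' A synergy is a superposition of N parametrized kernels per actuator
#' dimension: Gaussians in the decaying phase variable s for discrete
#' movements, von Mises bumps in the cyclic phase angle phi for rhythmic
#' movements.  Each kernel carries three free parameters: an amplitude
#' \eqn{a_{m,n}}, a mean \eqn{\mu_{m,n}} and a bandwidth \eqn{h_{m,n}}.
#' Unlike classical movement-primitive basis functions, all three are
#' learnable, and a whole synergy can be shifted in phase as a unit.
#'
#' @name basis
NULL

#' Evaluate a parametrized Gaussian kernel (discrete movements)
#'
#' Computes \eqn{a \exp(-(s - \mu + \Delta s)^2 / (2 h^2))}.  The shift
#' enters additively inside the kernel argument, so shifting the phase and
#' shifting the kernel are interchangeable.
#'
#' @param s Phase value(s); the decaying time abstraction in (0, 1].
#' @param a Amplitude (may be negative; sign constraints such as muscle
#'   excitation non-negativity are enforced downstream by clipping).
#' @param mu Kernel mean, in phase units.
#' @param h Bandwidth (standard-deviation-like), strictly positive.
#' @param shift Phase shift added inside the kernel argument. Default 0.
#' @return Numeric vector of kernel values, same length as `s`.
#' @export
eval_gaussian <- function(s, a, mu, h, shift = 0) {
  if (any(h <= 0)) stop("bandwidth `h` must be strictly positive")
  a * exp(-((s - mu + shift)^2) / (2 * h^2))
}

#' Evaluate a parametrized von Mises kernel (rhythmic movements)
#'
#' Computes \eqn{a \exp(h (\cos(\phi - \mu + \Delta s) - 1))}.  The exponent
#' is \eqn{h(\cos(\cdot) - 1)}, which is bounded in \eqn{[-2h, 0]} so the
#' kernel value lies in (0, a] for positive amplitude, peaking at
#' \eqn{\phi = \mu - \Delta s} (mod 2\eqn{\pi}).
#'
#' @param phi Phase angle(s) in radians; 2pi-periodic.
#' @param a Amplitude.
#' @param mu Kernel mean angle.
#' @param h Concentration (bandwidth), strictly positive.
#' @param shift Phase shift added inside the kernel argument. Default 0.
#' @return Numeric vector of kernel values.
#' @export
eval_von_mises <- function(phi, a, mu, h, shift = 0) {
  if (any(h <= 0)) stop("bandwidth `h` must be strictly positive")
  a * exp(h * (cos(phi - mu + shift) - 1))
}

#' Construct a synergy shape
#'
#' A synergy shape holds, for each actuator dimension d = 1..D, the
#' parameters of N kernels.  All dimensions share the same kernel count and
#' kind; the parameters themselves differ per dimension, which is what makes
#' a synergy a spatiotemporal pattern across actuators rather than a single
#' temporal profile.
#'
#' @param kind `"discrete"` (Gaussian kernels in s) or `"rhythmic"`
#'   (von Mises kernels in phi).
#' @param amplitudes,means,bandwidths Numeric N x D matrices (rows: kernels,
#'   columns: actuator dimensions).  Vectors are accepted for D = 1.
#'   Rhythmic means are stored modulo 2pi.
#' @return An object of class `"synergy_shape"` with elements `kind`,
#'   `amplitudes`, `means`, `bandwidths`, `N`, `D`.
#' @export
synergy_shape <- function(kind = c("discrete", "rhythmic"),
                          amplitudes, means, bandwidths) {
  kind <- match.arg(kind)
  amplitudes <- as.matrix(amplitudes)
  means <- as.matrix(means)
  bandwidths <- as.matrix(bandwidths)
  if (!all(dim(amplitudes) == dim(means)) ||
      !all(dim(amplitudes) == dim(bandwidths))) {
    stop("amplitudes, means and bandwidths must have identical dimensions")
  }
  if (any(bandwidths <= 0)) stop("all bandwidths must be strictly positive")
  if (kind == "rhythmic") means <- means %% (2 * pi)
  structure(
    list(kind = kind, amplitudes = amplitudes, means = means,
         bandwidths = bandwidths,
         N = nrow(amplitudes), D = ncol(amplitudes)),
    class = "synergy_shape")
}

#' @export
print.synergy_shape <- function(x, ...) {
  cat(sprintf("<synergy_shape> %s, N = %d kernel(s) x D = %d dimension(s)\n",
              x$kind, x$N, x$D))
  invisible(x)
}

#' Evaluate one synergy dimension at given phases
#'
#' Sums the N kernel values of dimension `d` at the (shifted) phase:
#' \eqn{\Lambda(s, \theta_{m,d}, \Delta s)} for discrete shapes,
#' \eqn{\Omega(\phi, \theta_{m,d}, \Delta s)} for rhythmic shapes.
#'
#' @param x Phase value(s): s for discrete shapes, phi for rhythmic.
#' @param shape A [synergy_shape()].
#' @param d Actuator dimension index, 1..D.
#' @param shift Phase shift applied to every kernel of this synergy.
#' @return Numeric vector of synergy values at `x`.
#' @export
eval_synergy <- function(x, shape, d = 1L, shift = 0) {
  stopifnot(inherits(shape, "synergy_shape"))
  if (d < 1L || d > shape$D) stop("dimension index `d` out of range")
  a <- shape$amplitudes[, d]
  mu <- shape$means[, d]
  h <- shape$bandwidths[, d]
  out <- numeric(length(x))
  kern <- if (shape$kind == "discrete") eval_gaussian else eval_von_mises
  for (n in seq_len(shape$N)) {
    out <- out + kern(x, a[n], mu[n], h[n], shift)
  }
  out
}

#' Evaluate all dimensions of a synergy at one or more phases
#'
#' Vector form of [eval_synergy()]: returns the length-D synergy vector
#' w_m at each phase, with either one shared shift (time-varying synergy
#' semantics) or one shift per dimension.
#'
#' @inheritParams eval_synergy
#' @param shift Scalar shift shared across dimensions, or a length-D vector
#'   of per-dimension shifts.
#' @return A `length(x)` x D matrix of synergy values.
#' @export
eval_synergy_matrix <- function(x, shape, shift = 0) {
  stopifnot(inherits(shape, "synergy_shape"))
  shift <- if (length(shift) == 1L) rep(shift, shape$D) else shift
  if (length(shift) != shape$D) stop("`shift` must be scalar or length D")
  out <- matrix(0, length(x), shape$D)
  for (d in seq_len(shape$D)) out[, d] <- eval_synergy(x, shape, d, shift[d])
  out
}
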