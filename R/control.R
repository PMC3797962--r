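#' Linear feedback control law
#'
#' Turns a desired trajectory into control commands by independent PD
#' tracking per actuator:
#' \deqn{u = \mathrm{diag}(k_{pos})(y^* - y) + \mathrm{diag}(k_{vel})(\dot y^* - \dot y).}
#'
#' @param y_des,yd_des Desired position and velocity, length D.
#' @param y,yd Simulated position and velocity, length D.
#' @param k_pos,k_vel Non-negative gains, scalar or length D.
#' @return Control vector u of length D.
#' @export
feedback_control <- function(y_des, yd_des, y, yd, k_pos, k_vel) {
  D <- length(y_des)
  if (length(yd_des) != D || length(y) != D || length(yd) != D) {
    stop("desired and simulated state vectors must have equal length")
  }
  k_pos <- rep_len(k_pos, D)
  k_vel <- rep_len(k_vel, D)
  k_pos * (y_des - y) + k_vel * (yd_des - yd)
}

#' One step of first-order muscle activation dynamics
#'
#' Muscles cannot generate force instantaneously: activation a lags the
#' neural excitation e through
#' \deqn{\dot a = (e^2 - e\,a)/\tau_{rise} + (e - a)/\tau_{fall},}
#' with a fast rise (default 10 ms) and a slower fall (default 40 ms).
#' The fixed point for constant e in [0, 1] is a = e.  Integrated with an
#' explicit Euler step and clamped to the physiological range [0, 1].
#'
#' @param a Current activation per muscle, in [0, 1].
#' @param e Excitation per muscle; expected to be clipped to [0, 1] by the
#'   caller (the synergy forcing can be negative).
#' @param dt Time step in seconds (> 0).
#' @param tau_rise,tau_fall Rise / fall time constants in seconds.
#' @return Updated activation vector, clamped to [0, 1].
#' @export
step_activation <- function(a, e, dt, tau_rise = 0.010, tau_fall = 0.040) {
  if (dt <= 0) stop("`dt` must be positive")
  stopifnot(tau_rise > 0, tau_fall > 0)
  adot <- (e^2 - e * a) / tau_rise + (e - a) / tau_fall
  pmin(pmax(a + dt * adot, 0), 1)
}

#' Integrate activation dynamics over an excitation trace
#'
#' Convenience wrapper applying [step_activation()] along the rows of an
#' excitation matrix.
#'
#' @param e T x D matrix of excitations (rows: time steps).
#' @param dt Time step in seconds.
#' @param a0 Initial activation (default 0).
#' @inheritParams step_activation
#' @return T x D matrix of activations; row t is the activation after
#'   processing excitation rows 1..t.
#' @export
activation_trace <- function(e, dt, a0 = 0, tau_rise = 0.010,
                             tau_fall = 0.040) {
  e <- as.matrix(e)
  a <- rep_len(a0, ncol(e))
  out <- matrix(NA_real_, nrow(e), ncol(e))
  for (t in seq_len(nrow(e))) {
    a <- step_activation(a, e[t, ], dt, tau_rise, tau_fall)
    out[t, ] <- a
  }
  out
}
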