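#' Steady-state activation sigmoid
#'
#' The logistic steady-state activation curve shared by all gating variables,
#' \code{zinf(V) = 1 / (1 + exp(-2 a (V - Vhalf)))}.
#'
#' @param V membrane voltage (mV); vectorized.
#' @param a slope constant (1/mV); positive for an activating gate.
#' @param Vhalf half-activation voltage (mV).
#' @return Activation fraction in (0, 1).
#' @export
steady_state_activation <- function(V, a, Vhalf) {
  1 / (1 + exp(-2 * a * (V - Vhalf)))
}

minf <- function(V, p) steady_state_activation(V, p$a_m, p$Vhalf_m)
ninf <- function(V, p) steady_state_activation(V, p$a_n, p$Vhalf_n)
xinf <- function(V, p) steady_state_activation(V, p$a_x, p$Vhalf_x)

#' Ionic currents of the conductance-based model
#'
#' Evaluates the five membrane currents at a given state: the
#' spike-generating sodium and potassium currents (gated by the shared
#' activation variable \code{n}), the leak, the high-voltage-activated calcium
#' current \code{ICa = gCa x^2 (V - VCa)} and the calcium-activated potassium
#' current \code{IKCa = gKCa C/(C + Kd) (V - VK)}.
#'
#' @param state named list or vector with \code{V}, \code{n}, \code{x},
#'   \code{C}.
#' @param p a \code{vn_parameters} object.
#' @return Named numeric vector \code{c(I_Na, I_K, I_leak, I_Ca, I_KCa)}
#'   (uA/cm^2); outward currents positive.
#' @export
ionic_currents <- function(state, p) {
  V <- state[["V"]]; n <- state[["n"]]; x <- state[["x"]]; C <- state[["C"]]
  c(I_Na  = p$gNa * minf(V, p)^3 * (1 - n) * (V - p$VNa),
    I_K   = p$gK * n^4 * (V - p$VK),
    I_leak = p$gL * (V - p$VL),
    I_Ca  = p$gCa * x^2 * (V - p$VCa),
    I_KCa = p$gKCa * C / (C + p$Kd) * (V - p$VK))
}

#' Steady-state calcium concentration
#'
#' \code{Cinf(V, x) = -KR * ICa(V, x)}: the calcium concentration towards which
#' \code{C} relaxes. Nonnegative whenever \code{V < VCa} (the calcium current
#' is inward there).
#'
#' @param V membrane voltage (mV); vectorized.
#' @param x calcium-channel activation fraction in [0, 1]; vectorized.
#' @param p a \code{vn_parameters} object.
#' @param warn warn if the result is negative (indicates \code{V > VCa},
#'   outside the operating range).
#' @return Steady-state concentration (same arbitrary units as \code{C}).
#' @export
calcium_steady_state <- function(V, x, p, warn = TRUE) {
  out <- -p$KR * p$gCa * x^2 * (V - p$VCa)
  if (warn && any(out < 0)) {
    warning("Cinf < 0: V exceeds VCa, outside the model's operating range")
  }
  out
}

#' Right-hand side of the 4-variable conductance-based model
#'
#' Time derivatives of \code{(V, n, x, C)} under constant bias current:
#' \code{Cm dV/dt = mu - (I_Na + I_K + I_leak + I_Ca + I_KCa)} with first-order
#' gating kinetics towards the steady-state activations and
#' \code{dC/dt = (Cinf(V, x) - C)/tau_C}.
#'
#' @param state named list or vector with \code{V}, \code{n}, \code{x},
#'   \code{C}.
#' @param mu bias current (uA/cm^2).
#' @param p a \code{vn_parameters} object.
#' @return Named numeric vector of derivatives \code{c(V =, n =, x =, C =)}.
#' @export
hh_rhs <- function(state, mu, p) {
  V <- state[["V"]]; n <- state[["n"]]; x <- state[["x"]]; C <- state[["C"]]
  I <- ionic_currents(state, p)
  c(V = (mu - sum(I)) / p$Cm,
    n = (ninf(V, p) - n) / p$tau_n,
    x = (xinf(V, p) - x) / p$tau_x,
    C = (calcium_steady_state(V, x, p, warn = FALSE) - C) / p$tau_C)
}

#' Right-hand side of the 3-variable adaptive QIF model
#'
#' The reduction replaces the sodium/potassium spike generator by the
#' quadratic term \code{psi(V) = g2 (V - V2)^2}:
#' \code{Cm dV/dt = mu + psi(V) - I_Ca(V, x) - I_KCa(V, C)}, with the same
#' \code{x} and \code{C} kinetics as the full model.
#'
#' @param state named list or vector with \code{V}, \code{x}, \code{C}.
#' @param mu bias current (uA/cm^2).
#' @param p a \code{vn_parameters} object.
#' @return Named numeric vector of derivatives \code{c(V =, x =, C =)}.
#' @export
qif_rhs <- function(state, mu, p) {
  V <- state[["V"]]; x <- state[["x"]]; C <- state[["C"]]
  ICa <- p$gCa * x^2 * (V - p$VCa)
  IKCa <- p$gKCa * C / (C + p$Kd) * (V - p$VK)
  c(V = (mu + p$g2 * (V - p$V2)^2 - ICa - IKCa) / p$Cm,
    x = (xinf(V, p) - x) / p$tau_x,
    C = (calcium_steady_state(V, x, p, warn = FALSE) - C) / p$tau_C)
}

#' Default initial state
#'
#' The packaged initial condition: reset voltage with gating variables at
#' their steady state for that voltage.
#'
#' @param p a \code{vn_parameters} object.
#' @param model \code{"hh"} (4 variables) or \code{"qif"} (3 variables).
#' @return Named numeric state vector.
#' @export
initial_state <- function(p, model = c("hh", "qif")) {
  model <- match.arg(model)
  V <- p$Vreset
  x <- xinf(V, p)
  C <- calcium_steady_state(V, x, p, warn = FALSE)
  if (model == "hh") c(V = V, n = ninf(V, p), x = x, C = C)
  else c(V = V, x = x, C = C)
}
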