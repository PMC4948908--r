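#' Artificial spike waveform
#'
#' The piecewise-linear voltage excursion used by the QIF model during the
#' refractory period: a linear rise from \code{Vth} to \code{Vmax} over
#' \code{t1} ms followed by a linear decay to \code{Vreset} at \code{tau_r} ms.
#' The high voltages it visits are what activate the calcium channel gate
#' between threshold crossing and reset.
#'
#' @param t time since the spike (ms), in \code{[0, tau_r]}; vectorized.
#' @param p a \code{vn_parameters} object (fields \code{Vth}, \code{Vmax},
#'   \code{Vreset}, \code{t1}, \code{tau_r}).
#' @return Voltage (mV).
#' @export
spike_waveform_value <- function(t, p) {
  if (any(t < 0 | t > p$tau_r)) {
    stop("t must lie within [0, tau_r]")
  }
  ifelse(t < p$t1,
         p$Vth + (p$Vmax - p$Vth) / p$t1 * t,
         p$Vmax + (p$Vreset - p$Vmax) / (p$tau_r - p$t1) * (t - p$t1))
}

#' Integrate the gating variables through the artificial spike
#'
#' Evolves only \code{x} and \code{C} (RK4, step \code{dt}) with the voltage
#' clamped to the spike waveform over \code{[0, tau_r]}, starting from the
#' values at threshold crossing. This is how the \code{"spike_waveform"} reset
#' rule produces state-dependent gating resets.
#'
#' @param x0,C0 gating values at the threshold crossing.
#' @param p a \code{vn_parameters} object.
#' @param dt internal integration step (ms).
#' @return Named vector \code{c(x_end, C_end, dx, dC)}: end-of-refractory
#'   values and the increments relative to \code{(x0, C0)}.
#' @export
integrate_gating_through_spike <- function(x0, C0, p, dt = 0.01) {
  stopifnot(x0 >= 0, x0 <= 1, C0 >= 0)
  e <- .gating_through_spike_cpp(par_vec(p), x0, C0, dt)
  c(x_end = unname(e["x_end"]), C_end = unname(e["C_end"]),
    dx = unname(e["x_end"]) - x0, dC = unname(e["C_end"]) - C0)
}

#' Gating reset rule
#'
#' Describes how the QIF gating variables are reset after a spike. Exactly the
#' constants of the active mode are interpreted: \code{dx}/\code{dC} for
#' \code{"fixed_delta"}, \code{x_reset}/\code{C_reset} for
#' \code{"fixed_reset"}; \code{"spike_waveform"} needs no constants (the reset
#' follows from integrating the gating variables through the artificial
#' spike).
#'
#' @param mode one of \code{"spike_waveform"}, \code{"fixed_delta"},
#'   \code{"fixed_reset"}.
#' @param dx,dC fixed gating increments (\code{"fixed_delta"}).
#' @param x_reset,C_reset fixed gating values (\code{"fixed_reset"}).
#' @return An object of class \code{vn_reset_rule}.
#' @export
reset_rule <- function(mode = c("spike_waveform", "fixed_delta",
                                "fixed_reset"),
                       dx = NULL, dC = NULL,
                       x_reset = NULL, C_reset = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed_delta" && (is.null(dx) || is.null(dC))) {
    stop("fixed_delta mode requires dx and dC")
  }
  if (mode == "fixed_reset" && is.null(x_reset)) {
    stop("fixed_reset mode requires x_reset (C_reset defaults to ",
         "Cinf(Vreset, x_reset))")
  }
  structure(list(mode = mode, dx = dx, dC = dC,
                 x_reset = x_reset, C_reset = C_reset),
            class = "vn_reset_rule")
}

apply_reset_rule <- function(p, rule) {
  stopifnot(inherits(rule, "vn_reset_rule"))
  p$reset_mode <- rule$mode
  if (rule$mode == "fixed_delta") {
    p$dx <- rule$dx
    p$dC <- rule$dC
  } else if (rule$mode == "fixed_reset") {
    p$x_reset <- rule$x_reset
    p$C_reset <- if (is.null(rule$C_reset)) {
      calcium_steady_state(p$Vreset, rule$x_reset, p)
    } else rule$C_reset
  }
  validate_parameters(p)
  p
}

#' Estimate the QIF parameters from the conductance-based model
#'
#' With \code{gCa = 0}, the subthreshold steady-state flow of the full model is
#' expanded to second order in voltage around \code{V0} (default -50 mV, the
#' approximate location of its local minimum): each activation nonlinearity
#' (\code{minf^3}, \code{ninf}, \code{ninf^4}) is Taylor-expanded as
#' \code{a + b (V - V0) + c (V - V0)^2}, the current products are collected
#' and truncated at second order, and the result written as
#' \code{mu + k + a (V - h)^2}. The quadratic coefficient plays the role of
#' \code{g2} and the vertex voltage the role of \code{V2}. (Keeping the gate
#' expansions only to first order cannot produce an upward-opening parabola:
#' the positive curvature is carried by the second-order gate terms multiplied
#' by the large sodium driving force.)
#'
#' @param p a \code{vn_parameters} object (its \code{gCa} is ignored; the
#'   expansion sets it to zero).
#' @param V0 expansion voltage (mV).
#' @return List with \code{g2}, \code{V2}, \code{k}, and the first-order gate
#'   coefficients \code{a1, b1, a2, b2, a3, b3}.
#' @export
estimate_qif_params <- function(p, V0 = -50) {
  m <- minf(V0, p); n <- ninf(V0, p)
  mp <- 2 * p$a_m * m * (1 - m)                 # dminf/dV
  np <- 2 * p$a_n * n * (1 - n)                 # dninf/dV
  mpp <- 2 * p$a_m * mp * (1 - 2 * m)           # d2minf/dV2
  npp <- 2 * p$a_n * np * (1 - 2 * n)           # d2ninf/dV2
  a1 <- m^3;  b1 <- 3 * m^2 * mp
  c1 <- (6 * m * mp^2 + 3 * m^2 * mpp) / 2      # half second derivative
  a2 <- n;    b2 <- np;   c2q <- npp / 2
  a3 <- n^4;  b3 <- 4 * n^3 * np
  c3 <- (12 * n^2 * np^2 + 4 * n^3 * npp) / 2
  A2 <- 1 - a2
  dNa <- V0 - p$VNa; dK <- V0 - p$VK; dL <- V0 - p$VL
  # m^3 (1 - n) expanded to u^2 (u = V - V0)
  p0 <- a1 * A2
  p1 <- b1 * A2 - a1 * b2
  p2 <- c1 * A2 - b1 * b2 - a1 * c2q
  k0 <- -p$gL * dL - p$gNa * p0 * dNa - p$gK * a3 * dK
  k1 <- -p$gL - p$gNa * (p0 + p1 * dNa) - p$gK * (a3 + b3 * dK)
  k2 <- -p$gNa * (p1 + p2 * dNa) - p$gK * (b3 + c3 * dK)
  if (k2 <= 0) {
    warning("expansion is not concave up at V0; no QIF vertex exists there")
  }
  V2 <- V0 - k1 / (2 * k2)
  k <- k0 - k1^2 / (4 * k2)
  list(g2 = k2, V2 = V2, k = k,
       a1 = a1, b1 = b1, a2 = a2, b2 = b2, a3 = a3, b3 = b3)
}
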