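#' Mean adaptation line
#'
#' Under the slow-gating approximation the calcium and calcium-activated
#' potassium currents, frozen at the reset gating values, combine into a
#' single adaptation current that is linear in voltage:
#' \code{W(V) = W0 + Wm V} with
#' \code{Wm = gCa x_r^2 + gKCa C_r/(C_r + Kd)} and
#' \code{W0 = -(gCa x_r^2 VCa + gKCa C_r/(C_r + Kd) VK)}.
#' Its slope is nonnegative, and both coefficients vanish when the calcium
#' pathway is silent (\code{gCa = 0} with \code{C_r = 0}).
#'
#' @param x_r calcium-gate reset value in [0, 1].
#' @param C_r calcium-concentration reset value (>= 0).
#' @param p a \code{vn_parameters} object.
#' @return List with \code{W0} (uA/cm^2) and \code{Wm} (mS/cm^2).
#' @export
adaptation_line <- function(x_r, C_r, p) {
  stopifnot(x_r >= 0, x_r <= 1, C_r >= 0)
  sCa <- p$gCa * x_r^2
  sK <- p$gKCa * C_r / (C_r + p$Kd)
  list(W0 = -(sCa * p$VCa + sK * p$VK), Wm = sCa + sK)
}

#' Reduced one-dimensional flow under the slow-gating approximation
#'
#' Voltage velocity \code{F(V) = (mu + g2 (V - V2)^2 - W0 - Wm V)/Cm} with
#' the gating variables frozen on the adaptation line.
#'
#' @param V voltage (mV); vectorized.
#' @param mu bias current (uA/cm^2).
#' @param line an \code{\link{adaptation_line}}.
#' @param p a \code{vn_parameters} object.
#' @return dV/dt (mV/ms).
#' @export
theory_F <- function(V, mu, line, p) {
  (mu + p$g2 * (V - p$V2)^2 - line$W0 - line$Wm * V) / p$Cm
}

# Completed-square variables of the reduced flow:
# mu + psi(V) - W(V) = mu_bar + g2 (V - V2_bar)^2.
square_vars <- function(mu, line, p) {
  V2_bar <- p$V2 + line$Wm / (2 * p$g2)
  mu_bar <- mu - line$W0 - line$Wm * p$V2 - line$Wm^2 / (4 * p$g2)
  list(mu_bar = mu_bar, V2_bar = V2_bar)
}

#' Tangency bias current
#'
#' The bias at which the depolarizing parabola \code{mu + psi(V) - eps}
#' becomes tangent to the adaptation line: above it the reduced flow
#' \code{F(V)} exceeds \code{eps} everywhere between reset and threshold and
#' the slow-gating interspike interval is a single arctan integral; below it
#' the trajectory stalls at the lower intersection and the interval
#' decomposes into three segments. Algebraically
#' \code{mu* = (2 g2 V2 + Wm)^2/(4 g2) - g2 V2^2 + W0 + eps}; when the
#' calcium pathway is silent this collapses to \code{eps}.
#'
#' @param p a \code{vn_parameters} object (uses \code{g2}, \code{V2},
#'   \code{eps}).
#' @param x_r,C_r gating reset values; default to the fixed-reset constants
#'   stored in \code{p}.
#' @return The tangency bias (uA/cm^2).
#' @export
mu_star <- function(p, x_r = p$x_reset, C_r = p$C_reset) {
  stopifnot(p$g2 > 0)
  line <- adaptation_line(x_r, C_r, p)
  (2 * p$g2 * p$V2 + line$Wm)^2 / (4 * p$g2) - p$g2 * p$V2^2 +
    line$W0 + p$eps
}

# definite integral of Cm / (mu_bar + g2 (V - V2_bar)^2), mu_bar > 0
.arc_integral <- function(lo, hi, mu_bar, V2_bar, p) {
  r <- sqrt(p$g2 / mu_bar)
  p$Cm / sqrt(p$g2 * mu_bar) *
    (atan(r * (hi - V2_bar)) - atan(r * (lo - V2_bar)))
}

#' Reset-to-threshold interval above the tangency bias
#'
#' Closed-form interspike interval of the reduced flow for \code{mu > mu*}:
#' the arctan integral of \code{1/F(V)} from \code{Vreset} to \code{Vth} in
#' the completed-square variables. As the calcium pathway shuts off the plain
#' QIF interval is recovered, and letting \code{g2 -> 0} gives the textbook
#' integrate-and-fire interval \code{(Vth - Vreset)/mu}.
#'
#' @param mu bias current (uA/cm^2).
#' @param line an \code{\link{adaptation_line}}.
#' @param p a \code{vn_parameters} object.
#' @return Interval (ms).
#' @export
interval_I0 <- function(mu, line, p) {
  sv <- square_vars(mu, line, p)
  if (sv$mu_bar <= 0) {
    stop("interval_I0 requires mu_bar > 0 (bias above the tangency point)")
  }
  .arc_integral(p$Vreset, p$Vth, sv$mu_bar, sv$V2_bar, p)
}

#' Stall voltage below the tangency bias
#'
#' For \code{mu < mu*}, the lower voltage at which the reduced flow drops to
#' the floor \code{eps}: the minus root of \code{F(V) = eps}. The trajectory
#' from reset slows to a crawl here and the slow gating variables take over.
#'
#' @inheritParams interval_I0
#' @return Voltage (mV).
#' @export
v_star <- function(mu, line, p) {
  b <- 2 * p$g2 * p$V2 + line$Wm
  disc <- b^2 - 4 * p$g2 * (mu - p$eps + p$g2 * p$V2^2 - line$W0)
  if (disc < 0) {
    stop("complex discriminant: mu exceeds the tangency bias, no stall point")
  }
  (b - sqrt(disc)) / (2 * p$g2)
}

#' Reset-to-stall interval below the tangency bias
#'
#' Closed-form travel time of the reduced flow from \code{Vreset} up to the
#' stall voltage \code{V*}, where the completed-square offset is negative and
#' the integral of \code{1/F} takes a logarithmic form.
#'
#' @inheritParams interval_I0
#' @param Vstar stall voltage; computed from \code{\link{v_star}} when NULL.
#' @return Interval (ms).
#' @export
interval_I1 <- function(mu, line, p, Vstar = NULL) {
  if (is.null(Vstar)) Vstar <- v_star(mu, line, p)
  sv <- square_vars(mu, line, p)
  if (Vstar < p$Vreset) stop("stall voltage below reset; no I1 segment")
  if (sv$mu_bar < 0) {
    # parabola minimum below the adaptation line: logarithmic form
    a <- sqrt(abs(sv$mu_bar))
    g <- sqrt(p$g2)
    G <- function(V) {
      u <- V - sv$V2_bar
      1 / (2 * g * a) * log(abs((g * u - a) / (g * u + a)))
    }
    p$Cm * (G(Vstar) - G(p$Vreset))
  } else if (sv$mu_bar > 0) {
    # narrow band mu* - eps < mu < mu*: F > 0 but dips below eps,
    # same arctan form as above the tangency point
    .arc_integral(p$Vreset, Vstar, sv$mu_bar, sv$V2_bar, p)
  } else {
    u1 <- p$Vreset - sv$V2_bar
    u2 <- Vstar - sv$V2_bar
    p$Cm / p$g2 * (1 / u1 - 1 / u2)
  }
}

#' Slow gating decay at the stall point
#'
#' Once the voltage stalls at \code{V*}, the gating variables relax: \code{x}
#' decays exponentially towards its steady state at the mid-segment voltage
#' \code{(V* + V2)/2}, and the calcium concentration follows either the
#' analytic exponential (constant-x approximation) or a forward-Euler
#' refinement that tracks the actual \code{x(t)} (capturing the transient
#' rise-then-fall of calcium that the exponential misses).
#'
#' @param x_r,C_r gating values when the stall begins.
#' @param Vstar stall voltage (mV).
#' @param p a \code{vn_parameters} object.
#' @param t_max horizon for the numeric trace (ms).
#' @param dt forward-Euler step (ms).
#' @return List with functions \code{x_t(t)} and \code{C_t(t)} (analytic),
#'   constants \code{x_inf_star}, \code{C_inf_star}, \code{V_bar_star}, and a
#'   numeric trace \code{C2} (data frame t, C) via forward Euler.
#' @export
gating_decay <- function(x_r, C_r, Vstar, p, t_max = 200, dt = 0.01) {
  V_bar_star <- (Vstar + p$V2) / 2
  x_inf_star <- xinf(V_bar_star, p)
  C_inf_star <- calcium_steady_state(Vstar, x_inf_star, p, warn = FALSE)
  x_t <- function(t) x_inf_star - (x_inf_star - x_r) * exp(-t / p$tau_x)
  C_t <- function(t) C_inf_star - (C_inf_star - C_r) * exp(-t / p$tau_C)
  tt <- seq(0, t_max, by = dt)
  C2 <- numeric(length(tt))
  C2[1] <- C_r
  for (i in seq_along(tt)[-1]) {
    Cinf_i <- calcium_steady_state(Vstar, x_t(tt[i - 1]), p, warn = FALSE)
    C2[i] <- C2[i - 1] + dt * (Cinf_i - C2[i - 1]) / p$tau_C
  }
  list(x_t = x_t, C_t = C_t, x_inf_star = x_inf_star,
       C_inf_star = C_inf_star, V_bar_star = V_bar_star,
       C2 = data.frame(t = tt, C = C2))
}

# numeric C decay evaluated at a single time (forward Euler, Eq-22 style)
.C2_at <- function(t, x_r, C_r, Vstar, p, dt = 0.01) {
  if (t <= 0) return(C_r)
  gd <- gating_decay(x_r, C_r, Vstar, p, t_max = t, dt = dt)
  utils::tail(gd$C2$C, 1)
}

#' Stall interval from the first-order adaptation decay
#'
#' Expands the adaptation current at the stall voltage to first order in
#' time: \code{A} is the adaptation current when the trajectory enters the
#' stall region and \code{B} its (negative) decay rate, both built from the
#' gating decay evaluated one time constant in. The stall interval is the
#' "distance over velocity" ratio \code{I* = (mu - eps - A)/B}, clamped at
#' zero outside the valid regime.
#'
#' @param mu bias current (uA/cm^2).
#' @param x_r,C_r gating values at the start of the stall.
#' @param p a \code{vn_parameters} object.
#' @param Vstar stall voltage; recomputed when NULL.
#' @param c_decay \code{"numeric"} (default; forward-Euler calcium trace) or
#'   \code{"analytic"} (exponential) for the calcium term of \code{B}.
#' @return List with \code{I_star} (ms), \code{A}, \code{B}, \code{a1},
#'   \code{a2}, \code{b1}, \code{b2}, \code{Vstar} and the
#'   \code{\link{gating_decay}} used.
#' @export
interval_Istar <- function(mu, x_r, C_r, p, Vstar = NULL,
                           c_decay = c("numeric", "analytic")) {
  c_decay <- match.arg(c_decay)
  line <- adaptation_line(x_r, C_r, p)
  if (is.null(Vstar)) Vstar <- v_star(mu, line, p)
  gd <- gating_decay(x_r, C_r, Vstar, p, t_max = p$tau_C, dt = 0.01)
  a1 <- x_r^2
  a2 <- C_r / (p$Kd + C_r)
  x_tau <- gd$x_t(p$tau_x)
  C_tau <- if (c_decay == "numeric") {
    utils::tail(gd$C2$C, 1)  # trace runs to tau_C
  } else {
    gd$C_t(p$tau_C)
  }
  b1 <- 2 * x_tau * (gd$x_inf_star - x_r) / p$tau_x * exp(-1)
  b2 <- p$Kd * (gd$C_inf_star - C_r) /
    ((p$Kd + C_tau)^2 * p$tau_C) * exp(-1)
  A <- p$gCa * a1 * (Vstar - p$VCa) + p$gKCa * a2 * (Vstar - p$VK)
  B <- p$gCa * b1 * (Vstar - p$VCa) + p$gKCa * b2 * (Vstar - p$VK)
  if (abs(B) < 1e-12) {
    stop("degenerate adaptation decay: B is numerically zero")
  }
  I_star <- (mu - p$eps - A) / B
  if (I_star < 0) I_star <- 0
  list(I_star = I_star, A = A, B = B, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
       Vstar = Vstar, decay = gd)
}

#' Vertex-to-threshold interval after the stall
#'
#' After the stall interval the gating variables have decayed to
#' \code{x*(t*)}, \code{C*(t*)}; a new adaptation line is anchored so that it
#' passes through the parabola vertex at height \code{mu - eps}, and the
#' remaining travel time from \code{V2} to threshold is again an arctan
#' integral in the re-completed square variables.
#'
#' @inheritParams interval_Istar
#' @param istar output of \code{\link{interval_Istar}}; recomputed when NULL.
#' @return List with \code{I2} (ms), the decayed gating values \code{x_end},
#'   \code{C_end}, the anchored line (\code{W0_star}, \code{Wm_star}) and the
#'   square variables (\code{mu_bar_star}, \code{V2_bar_star}).
#' @export
interval_I2 <- function(mu, x_r, C_r, p, istar = NULL,
                        c_decay = c("numeric", "analytic"),
                        extend_stall = TRUE) {
  c_decay <- match.arg(c_decay)
  if (is.null(istar)) istar <- interval_Istar(mu, x_r, C_r, p,
                                              c_decay = c_decay)
  t_max <- 20 * p$tau_C
  gd <- gating_decay(x_r, C_r, istar$Vstar, p, t_max = t_max, dt = 0.01)
  C_at <- if (c_decay == "numeric") {
    function(t) stats::approx(gd$C2$t, gd$C2$C, t, rule = 2)$y
  } else {
    gd$C_t
  }
  Wm_at <- function(t) {
    p$gCa * gd$x_t(t)^2 + p$gKCa * C_at(t) / (p$Kd + C_at(t))
  }
  I2_at <- function(t) {
    Wm <- Wm_at(t)
    line2 <- list(W0 = mu - p$eps - Wm * p$V2, Wm = Wm)
    sv <- square_vars(mu, line2, p)
    if (sv$mu_bar <= 0) return(Inf)
    .arc_integral(p$V2, p$Vth, sv$mu_bar, sv$V2_bar, p)
  }
  t_star <- istar$I_star
  Wm_crit <- sqrt(4 * p$g2 * p$eps)
  if (Wm_at(t_star) >= Wm_crit) {
    # the anchored line still crosses the parabola below threshold at the
    # first-order stall time: the gating variables keep decaying, and the
    # trajectory leaves along the fastest consistent path (minimum of
    # stall time + remaining travel time)
    if (!extend_stall || Wm_at(t_max) >= Wm_crit) {
      stop("mu_bar* <= 0: anchored adaptation line re-crosses the parabola ",
           "before threshold")
    }
    tg <- seq(t_star, t_max, length.out = 400L)
    tot <- tg + vapply(tg, I2_at, numeric(1))
    i <- which.min(tot)
    lo <- tg[max(1L, i - 1L)]; hi <- tg[min(length(tg), i + 1L)]
    t_star <- stats::optimize(function(t) t + I2_at(t), c(lo, hi))$minimum
  }
  Wm_star <- Wm_at(t_star)
  x_end <- gd$x_t(t_star)
  C_end <- C_at(t_star)
  W0_star <- mu - p$eps - Wm_star * p$V2
  line2 <- list(W0 = W0_star, Wm = Wm_star)
  sv <- square_vars(mu, line2, p)
  if (sv$mu_bar <= 0) {
    stop("mu_bar* <= 0: anchored adaptation line re-crosses the parabola ",
         "before threshold")
  }
  I2 <- .arc_integral(p$V2, p$Vth, sv$mu_bar, sv$V2_bar, p)
  list(I2 = I2, x_end = x_end, C_end = C_end, t_star = t_star,
       W0_star = W0_star, Wm_star = Wm_star,
       mu_bar_star = sv$mu_bar, V2_bar_star = sv$V2_bar)
}

#' Full interval decomposition at one bias
#'
#' Dispatches on the bias relative to the tangency point \code{mu*}: above it
#' a single reset-to-threshold interval; below it the three-segment
#' decomposition (reset-to-stall, stall, vertex-to-threshold).
#'
#' @inheritParams interval_Istar
#' @return List with \code{branch} ("case1"/"case2"), \code{mu_star},
#'   \code{isi_sub} (subthreshold interval, ms), \code{isi} (with refractory
#'   period), and per-branch components.
#' @export
theory_intervals <- function(mu, x_r, C_r, p,
                             c_decay = c("numeric", "analytic")) {
  c_decay <- match.arg(c_decay)
  line <- adaptation_line(x_r, C_r, p)
  ms <- mu_star(p, x_r, C_r)
  if (mu > ms) {
    I0 <- interval_I0(mu, line, p)
    list(branch = "case1", mu_star = ms, I0 = I0,
         isi_sub = I0, isi = I0 + p$tau_r)
  } else {
    Vs <- v_star(mu, line, p)
    if (Vs <= p$Vreset) {
      # reset already inside the stalled region: no free-drift segment
      Vs <- p$Vreset
      I1 <- 0
    } else {
      I1 <- interval_I1(mu, line, p, Vstar = Vs)
    }
    ist <- interval_Istar(mu, x_r, C_r, p, Vstar = Vs, c_decay = c_decay)
    i2 <- interval_I2(mu, x_r, C_r, p, istar = ist, c_decay = c_decay)
    isi_sub <- I1 + i2$t_star + i2$I2
    list(branch = "case2", mu_star = ms, I1 = I1, I_star = i2$t_star,
         I2 = i2$I2, Vstar = Vs, A = ist$A, B = ist$B,
         x_end = i2$x_end, C_end = i2$C_end,
         isi_sub = isi_sub, isi = isi_sub + p$tau_r)
  }
}

#' Analytic steady-state firing rate over a bias sweep
#'
#' The slow-gating firing rate for the fixed-reset QIF: below the tangency
#' bias the interval is the three-segment decomposition, above it the single
#' arctan interval; the rate is the reciprocal interval, reported both with
#' the refractory period and without it.
#'
#' @param mu_grid bias currents (uA/cm^2).
#' @param p a \code{vn_parameters} object (fixed-reset constants
#'   \code{x_reset}, \code{C_reset} used unless overridden).
#' @param x_r,C_r gating reset values.
#' @param c_decay calcium-decay variant for the stall segment.
#' @return A data frame of class \code{vn_theory}: per bias, the branch, the
#'   intervals (ms), \code{R_tau} and \code{R_0} (spk/ms, with and without
#'   refractory period), \code{rate_tau} and \code{rate_0} (spk/s), and
#'   \code{mu_star} (constant column). Biases where the decomposition fails
#'   carry NA intervals.
#' @export
firing_rate_theory <- function(mu_grid, p, x_r = p$x_reset,
                               C_r = p$C_reset,
                               c_decay = c("numeric", "analytic")) {
  c_decay <- match.arg(c_decay)
  ms <- mu_star(p, x_r, C_r)
  rows <- lapply(mu_grid, function(mu) {
    th <- tryCatch(theory_intervals(mu, x_r, C_r, p, c_decay = c_decay),
                   error = function(e) NULL)
    if (is.null(th)) {
      return(data.frame(mu = mu, branch = NA_character_, I0 = NA_real_,
                        I1 = NA_real_, I_star = NA_real_, I2 = NA_real_,
                        isi_sub = NA_real_, R_tau = NA_real_, R_0 = NA_real_))
    }
    data.frame(mu = mu, branch = th$branch,
               I0 = if (th$branch == "case1") th$I0 else NA_real_,
               I1 = if (th$branch == "case2") th$I1 else NA_real_,
               I_star = if (th$branch == "case2") th$I_star else NA_real_,
               I2 = if (th$branch == "case2") th$I2 else NA_real_,
               isi_sub = th$isi_sub,
               R_tau = 1 / (th$isi_sub + p$tau_r),
               R_0 = 1 / th$isi_sub)
  })
  out <- do.call(rbind, rows)
  out$rate_tau <- 1000 * out$R_tau
  out$rate_0 <- 1000 * out$R_0
  out$mu_star <- ms
  class(out) <- c("vn_theory", class(out))
  out
}

#' Gain of the analytic rate and its closed-form approximations
#'
#' The gain is the slope of the rate-versus-bias curve. It is computed by
#' central finite differences of the analytic rate (both refractory variants)
#' and compared with the two closed-form approximations: below the tangency
#' bias, \code{G-} treats the stall interval as dominant (the reset-to-stall
#' and vertex-to-threshold intervals enter as the constant \code{2*pi} ms, as
#' printed in the source derivation, or as their computed values when
#' \code{printed_constants = FALSE}), giving an inverse-square divergence at
#' a bias near \code{mu*}; above it, \code{G+} scales as the inverse square
#' root of the completed-square offset.
#'
#' @param theory a \code{vn_theory} data frame from
#'   \code{\link{firing_rate_theory}}.
#' @param p a \code{vn_parameters} object.
#' @param x_r,C_r the reset values used for the theory sweep.
#' @param printed_constants use the literal \code{I1 + I2 ~ 2*pi} ms
#'   approximation inside \code{G-} (default) instead of the computed
#'   intervals.
#' @return A data frame: \code{mu}, \code{G_tau}, \code{G_0} (finite
#'   differences, spk/ms per uA/cm^2), \code{G_minus}, \code{G_plus}
#'   (closed forms; NA off-branch), and the divergence locations
#'   \code{mu_div_minus}, \code{mu_div_plus} as attributes.
#' @export
theory_gain <- function(theory, p, x_r = p$x_reset, C_r = p$C_reset,
                        printed_constants = TRUE) {
  mu <- theory$mu
  ms <- theory$mu_star[1]
  G_tau <- .central_diff(mu, theory$R_tau)
  G_0 <- .central_diff(mu, theory$R_0)
  line <- adaptation_line(x_r, C_r, p)
  G_minus <- rep(NA_real_, length(mu))
  G_plus <- rep(NA_real_, length(mu))
  mu_div_minus <- rep(NA_real_, length(mu))
  for (i in seq_along(mu)) {
    if (!is.na(theory$branch[i]) && theory$branch[i] == "case2") {
      ist <- tryCatch(interval_Istar(mu[i], x_r, C_r, p),
                      error = function(e) NULL)
      if (!is.null(ist)) {
        rest <- if (printed_constants) 2 * pi else
          theory$I1[i] + theory$I2[i]
        # G- = -(1/(I* + rest)^2) dI*/dmu with dI*/dmu = 1/B (B < 0)
        G_minus[i] <- abs(ist$B) / (mu[i] - p$eps - ist$A + rest * ist$B)^2
        mu_div_minus[i] <- ist$A + p$eps - rest * ist$B
      }
    } else if (!is.na(theory$branch[i])) {
      sv <- square_vars(mu[i], line, p)
      if (sv$mu_bar > 0) {
        G_plus[i] <- sqrt(p$g2 / sv$mu_bar) / (2 * pi)
      }
    }
  }
  out <- data.frame(mu = mu, G_tau = G_tau, G_0 = G_0,
                    G_minus = G_minus, G_plus = G_plus)
  attr(out, "mu_star") <- ms
  attr(out, "mu_div_minus") <- mu_div_minus
  attr(out, "mu_div_plus") <- ms - p$eps  # where mu_bar -> 0
  out
}

.central_diff <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(rep(NA_real_, n))
  g <- rep(NA_real_, n)
  g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  g
}

#' Normalized gain error curves
#'
#' Absolute difference between the theoretical gain and a reference gain,
#' normalized by the reference, per branch; entries where the reference gain
#' is ~0 are NA.
#'
#' @param gain_theory,gain_ref numeric vectors on a common bias grid.
#' @param branch optional branch labels to split the summary.
#' @return List with \code{error} (vector) and, when branches are given,
#'   \code{by_branch} mean errors.
#' @export
theory_error_curves <- function(gain_theory, gain_ref, branch = NULL) {
  stopifnot(length(gain_theory) == length(gain_ref))
  err <- abs(gain_theory - gain_ref) / abs(gain_ref)
  err[!is.finite(err) | abs(gain_ref) < 1e-12] <- NA_real_
  out <- list(error = err)
  if (!is.null(branch)) {
    out$by_branch <- tapply(err, branch, mean, na.rm = TRUE)
  }
  out
}
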