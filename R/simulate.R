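#' Simulate the conductance-based model
#'
#' Integrates the 4-variable system (V, n, x, C) under a constant bias current.
#' The default integrator is a fixed-step 4th-order Runge-Kutta scheme compiled
#' in C++ (bit-reproducible for identical inputs); an adaptive LSODA
#' integrator (via \pkg{deSolve}) is available behind the same contract for
#' convergence cross-checks.
#'
#' @param p a \code{vn_parameters} object.
#' @param mu constant bias current (uA/cm^2).
#' @param duration simulated time (ms).
#' @param dt integration step (ms) for the fixed-step integrator; also the
#'   output sampling step of the adaptive integrator.
#' @param init initial state \code{c(V, n, x, C)}; defaults to
#'   \code{\link{initial_state}}.
#' @param vdetect voltage whose upward crossings are registered as spike times
#'   (mV); crossings are linearly interpolated within the step.
#' @param record keep the full state trace (set \code{FALSE} for sweeps where
#'   only spike times are needed).
#' @param thin keep every \code{thin}-th sample of the trace.
#' @param integrator \code{"rk4"} (fixed-step, default) or \code{"lsoda"}
#'   (adaptive).
#' @param guard minimal separation between detected spikes (ms); closer
#'   crossings are merged.
#' @return A \code{vn_trace} object: list with \code{times}, \code{states}
#'   (matrix with columns V, n, x, C), \code{spike_times}, \code{mu},
#'   \code{dt}, \code{model = "hh"}, \code{integrator_id}.
#' @export
simulate_hh <- function(p, mu, duration, dt = 0.01, init = NULL,
                        vdetect = 0, record = TRUE, thin = 1L,
                        integrator = c("rk4", "lsoda"), guard = 1) {
  stopifnot(inherits(p, "vn_parameters"), duration > 0, dt > 0)
  integrator <- match.arg(integrator)
  if (is.null(init)) init <- initial_state(p, "hh")
  if (integrator == "rk4") {
    res <- .hh_integrate_cpp(par_vec(p), mu, duration, dt,
                             as.numeric(init[c("V", "n", "x", "C")]),
                             vdetect, record, as.integer(thin), guard)
    states <- if (record) {
      cbind(V = res$V, n = res$n, x = res$x, C = res$C)
    } else NULL
    times <- if (record) res$times else NULL
    spikes <- res$spike_times
  } else {
    times <- seq(0, duration, by = dt * thin)
    sol <- deSolve::lsoda(
      y = c(V = unname(init[["V"]]), n = unname(init[["n"]]),
            x = unname(init[["x"]]), C = unname(init[["C"]])),
      times = times,
      func = function(t, y, parms) list(unname(hh_rhs(y, mu, p))),
      rtol = 1e-9, atol = 1e-9)
    states <- unname(sol[, -1, drop = FALSE])
    colnames(states) <- c("V", "n", "x", "C")
    spikes <- .crossings(times, states[, "V"], vdetect, guard)
    if (!record) states <- NULL
  }
  new_trace(times, states, spikes, mu, dt, "hh",
            paste0(integrator, if (integrator == "rk4") sprintf("_dt%g", dt)))
}

#' Simulate the adaptive QIF model
#'
#' Integrates the 3-variable reduction (V, x, C) with threshold/reset boundary
#' conditions. When V reaches \code{Vth} a spike is recorded (crossing time
#' interpolated within the step) and the gating variables are reset according
#' to the active rule: \code{"spike_waveform"} integrates x and C through the
#' piecewise-linear artificial spike, \code{"fixed_delta"} adds fixed
#' increments, \code{"fixed_reset"} sets fixed values. In the two fixed modes
#' the gating variables are frozen during the refractory period and set at its
#' end. The voltage resumes at \code{Vreset} a refractory period after the
#' crossing. Recorded traces contain the subthreshold samples plus a sample
#' clamped at \code{Vth} at each spike.
#'
#' @inheritParams simulate_hh
#' @param reset_rule optional \code{\link{reset_rule}} overriding the mode and
#'   reset constants stored in \code{p}.
#' @param init initial state \code{c(V, x, C)}.
#' @return A \code{vn_trace} object (\code{model = "qif"}) whose
#'   \code{x_at_reset}/\code{C_at_reset} fields record the gating values
#'   applied after each spike.
#' @export
simulate_qif <- function(p, mu, duration, dt = 0.01, init = NULL,
                         reset_rule = NULL, record = TRUE, thin = 1L) {
  stopifnot(inherits(p, "vn_parameters"), duration > 0, dt > 0)
  if (!is.null(reset_rule)) p <- apply_reset_rule(p, reset_rule)
  if (is.null(init)) init <- initial_state(p, "qif")
  mode <- match(p$reset_mode, c("spike_waveform", "fixed_delta",
                                "fixed_reset")) - 1L
  res <- .qif_integrate_cpp(par_vec(p), mu, duration, dt,
                            as.numeric(init[c("V", "x", "C")]),
                            mode, record, as.integer(thin))
  states <- if (record) cbind(V = res$V, x = res$x, C = res$C) else NULL
  tr <- new_trace(if (record) res$times else NULL, states, res$spike_times,
                  mu, dt, "qif", sprintf("rk4_dt%g", dt))
  tr$reset_mode <- p$reset_mode
  tr$x_at_reset <- res$x_at_reset
  tr$C_at_reset <- res$C_at_reset
  tr
}

new_trace <- function(times, states, spikes, mu, dt, model, integrator_id) {
  structure(list(times = times, states = states, spike_times = spikes,
                 mu = mu, dt = dt, model = model,
                 integrator_id = integrator_id),
            class = "vn_trace")
}

#' @export
print.vn_trace <- function(x, ...) {
  cat(sprintf("<vn_trace> model=%s mu=%g dt=%g integrator=%s\n",
              x$model, x$mu, x$dt, x$integrator_id))
  if (!is.null(x$times)) {
    cat(sprintf("  %d samples over %.6g ms\n", length(x$times),
                max(x$times)))
  }
  cat(sprintf("  %d spikes\n", length(x$spike_times)))
  invisible(x)
}

# Upward crossings of `level` with linear interpolation; crossings closer than
# `guard` ms are merged.
.crossings <- function(times, V, level, guard = 1) {
  n <- length(V)
  if (n < 2L) return(numeric(0))
  below <- V[-n] < level & V[-1] >= level
  idx <- which(below)
  if (!length(idx)) return(numeric(0))
  tc <- times[idx] + (times[idx + 1] - times[idx]) *
    (level - V[idx]) / (V[idx + 1] - V[idx])
  keep <- c(TRUE, diff(tc) > guard)
  # guard must apply sequentially, not pairwise
  out <- numeric(0)
  last <- -Inf
  for (t in tc) {
    if (t - last > guard) {
      out <- c(out, t)
      last <- t
    }
  }
  out
}

#' Detect spikes in a recorded trace
#'
#' Returns the times at which the voltage crosses \code{vdetect} upward,
#' linearly interpolated between samples; crossings closer than \code{guard}
#' ms are merged into one.
#'
#' @param trace a \code{vn_trace} with a recorded voltage.
#' @param vdetect detection voltage (mV).
#' @param guard refractory merge window (ms).
#' @return Numeric vector of spike times (ms); possibly empty.
#' @export
detect_spikes <- function(trace, vdetect = 0, guard = 1) {
  stopifnot(inherits(trace, "vn_trace"), !is.null(trace$states))
  .crossings(trace$times, trace$states[, "V"], vdetect, guard)
}
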