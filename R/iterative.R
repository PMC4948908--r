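#' Subthreshold voltage occupancy density
#'
#' For a bias above the tangency point the reduced flow is positive between
#' reset and threshold, and the steady-state voltage density of the
#' freely-drifting trajectory is proportional to the time spent per voltage,
#' \code{1/F(V)}; its normalization constant is the subthreshold interspike
#' interval.
#'
#' @param mu bias current (uA/cm^2).
#' @param x_r,C_r gating values defining the adaptation line.
#' @param p a \code{vn_parameters} object.
#' @param n grid points.
#' @return A \code{vn_density}: list with \code{support}, \code{density}
#'   (integrates to 1) and \code{norm} (the interval I0, ms).
#' @export
subthreshold_density <- function(mu, x_r, C_r, p, n = 2000L) {
  line <- adaptation_line(x_r, C_r, p)
  V <- seq(p$Vreset, p$Vth, length.out = n)
  Fv <- theory_F(V, mu, line, p)
  if (any(Fv <= 0)) {
    stop("F(V) <= 0 inside the subthreshold window: the occupancy density ",
         "only exists above the tangency bias")
  }
  w <- 1 / Fv
  # adaptive quadrature for the normalization constant (the interval I0)
  norm <- stats::integrate(function(v) 1 / theory_F(v, mu, line, p),
                           p$Vreset, p$Vth, rel.tol = 1e-12)$value
  structure(list(support = V, density = w / .trapz(V, w), norm = norm),
            class = "vn_density")
}

.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Voltage occupancy density of the artificial spike
#'
#' Time-occupancy density of the piecewise-linear spike waveform over the
#' refractory period: the rising branch spreads \code{t1/tau_r} of the mass
#' uniformly over \code{[Vth, Vmax]}, the falling branch spreads the rest
#' uniformly over \code{[Vreset, Vmax]} (constant slopes mean constant
#' occupancy per branch).
#'
#' @param p a \code{vn_parameters} object.
#' @param n grid points.
#' @return A \code{vn_density} over \code{[Vreset, Vmax]}.
#' @export
spike_density <- function(p, n = 500L) {
  V <- seq(p$Vreset, p$Vmax, length.out = n)
  d <- numeric(n)
  rise <- V >= p$Vth
  d[rise] <- d[rise] + (p$t1 / p$tau_r) / (p$Vmax - p$Vth)
  d <- d + ((p$tau_r - p$t1) / p$tau_r) / (p$Vmax - p$Vreset)
  structure(list(support = V, density = d / .trapz(V, d), norm = p$tau_r),
            class = "vn_density")
}

#' Combined subthreshold + spike voltage density
#'
#' Mixture of the subthreshold and spike-waveform densities weighted by the
#' fraction of the full interspike interval each phase occupies,
#' renormalized on the common support.
#'
#' @param p0 subthreshold \code{vn_density}.
#' @param pspk spike-waveform \code{vn_density}.
#' @param I0 subthreshold interval (ms).
#' @param tau_r refractory period (ms).
#' @param n grid points of the common support.
#' @return A \code{vn_density} over the union support.
#' @export
combined_density <- function(p0, pspk, I0, tau_r, n = 2500L) {
  lo <- min(p0$support[1], pspk$support[1])
  hi <- max(p0$support[length(p0$support)],
            pspk$support[length(pspk$support)])
  V <- seq(lo, hi, length.out = n)
  f0 <- stats::approx(p0$support, p0$density, V, yleft = 0, yright = 0,
                      rule = 1)$y
  f0[is.na(f0)] <- 0
  fs <- stats::approx(pspk$support, pspk$density, V, yleft = 0, yright = 0,
                      rule = 1)$y
  fs[is.na(fs)] <- 0
  w0 <- I0 / (I0 + tau_r)
  d <- w0 * f0 + (1 - w0) * fs
  structure(list(support = V, density = d / .trapz(V, d),
                 norm = I0 + tau_r),
            class = "vn_density")
}

#' Self-consistent mean gating values under a voltage density
#'
#' Quadrature of the steady-state gate and calcium curves against a voltage
#' occupancy density: \code{<x> = int xinf(V) p(V) dV} and
#' \code{<C> = int Cinf(V, xinf(V)) p(V) dV}.
#'
#' @param dens a \code{vn_density}.
#' @param p a \code{vn_parameters} object.
#' @return Named vector \code{c(x = , C = )}.
#' @export
self_consistent_means <- function(dens, p) {
  V <- dens$support
  xs <- xinf(V, p)
  Cs <- calcium_steady_state(V, xs, p, warn = FALSE)
  c(x = .trapz(V, xs * dens$density),
    C = .trapz(V, Cs * dens$density))
}

#' Iterative self-consistent reset prediction for the spike-waveform QIF
#'
#' When the gating resets are generated by the artificial spike they are not
#' known in advance. Starting from an initial guess, each iteration computes
#' the tangency bias for the current resets and takes one of two routes:
#' above it (free drift), the interspike interval is the single arctan
#' integral and the next resets are the mean gating values under the combined
#' subthreshold + spike voltage density (a self-consistency step); below it
#' (stalled drift), the interval is the three-segment decomposition, the
#' gating variables decay through the stall, and the next resets come from
#' integrating the decayed values through the artificial spike. The resulting
#' ISI sequence may settle to a single value, a repeating block (bursting) or
#' no repeating pattern; the retained block is classified through the ISI
#' return map machinery.
#'
#' @param mu bias current (uA/cm^2).
#' @param p a \code{vn_parameters} object.
#' @param n_transient iterations discarded before classification.
#' @param n_keep retained iterations.
#' @param init initial resets \code{c(x, C)}; defaults to the steady-state
#'   values at the reset voltage. The algorithm is deterministic.
#' @param c_decay calcium-decay variant inside the stall segment.
#' @param rel_tol ISI equality tolerance for the periodicity classification.
#' @return A list of class \code{vn_iteration}: \code{log} (data frame with
#'   iteration, branch, resets in/out, ISI), \code{isis} (retained ISIs),
#'   \code{class} (\code{"one_spk"}, \code{"periodic_N"}, \code{"aperiodic"}),
#'   \code{period}, \code{rate_mean}, \code{rate_sd} (spk/s over retained
#'   1/ISI), \code{mu}, \code{failed} (TRUE when a step was numerically
#'   infeasible and iteration stopped early).
#' @export
iterate_qif_theory <- function(mu, p, n_transient = 20L, n_keep = 20L,
                               init = NULL, c_decay = "numeric",
                               rel_tol = 1e-3) {
  if (is.null(init)) {
    x0 <- xinf(p$Vreset, p)
    init <- c(x = x0, C = calcium_steady_state(p$Vreset, x0, p, warn = FALSE))
  }
  x_r <- unname(init[1]); C_r <- unname(init[2])
  n_tot <- n_transient + n_keep
  log <- vector("list", n_tot)
  failed <- FALSE
  for (k in seq_len(n_tot)) {
    step <- tryCatch(
      .iterate_step(mu, x_r, C_r, p, c_decay),
      error = function(e) NULL)
    if (is.null(step) || !all(is.finite(c(step$isi, step$x_out,
                                          step$C_out)))) {
      failed <- TRUE
      log <- log[seq_len(k - 1L)]
      break
    }
    log[[k]] <- data.frame(iteration = k, branch = step$branch,
                           x_in = x_r, C_in = C_r,
                           isi = step$isi,
                           x_out = step$x_out, C_out = step$C_out)
    x_r <- step$x_out; C_r <- step$C_out
  }
  log_df <- do.call(rbind, log)
  isis <- if (!is.null(log_df) && nrow(log_df) > n_transient) {
    log_df$isi[(n_transient + 1L):nrow(log_df)]
  } else numeric(0)
  cls <- .classify_block(isis, rel_tol)
  rates <- if (length(isis)) 1000 / isis else numeric(0)
  structure(list(log = log_df, isis = isis, class = cls$class,
                 period = cls$period,
                 rate_mean = if (length(rates)) mean(rates) else NA_real_,
                 rate_sd = if (length(rates) > 1) sd(rates) else NA_real_,
                 mu = mu, failed = failed),
            class = "vn_iteration")
}

.iterate_step <- function(mu, x_r, C_r, p, c_decay) {
  ms <- mu_star(p, x_r, C_r)
  if (mu > ms) {
    line <- adaptation_line(x_r, C_r, p)
    I0 <- interval_I0(mu, line, p)
    p0 <- subthreshold_density(mu, x_r, C_r, p)
    ps <- spike_density(p)
    pc <- combined_density(p0, ps, I0, p$tau_r)
    m <- self_consistent_means(pc, p)
    list(branch = "case1", isi = I0 + p$tau_r,
         x_out = unname(m["x"]), C_out = unname(m["C"]))
  } else {
    th <- theory_intervals(mu, x_r, C_r, p, c_decay = c_decay)
    # decayed gating values ride unchanged from the vertex to threshold,
    # then through the artificial spike
    e <- integrate_gating_through_spike(th$x_end, th$C_end, p)
    list(branch = "case2", isi = th$isi,
         x_out = unname(e["x_end"]), C_out = unname(e["C_end"]))
  }
}

.classify_block <- function(isis, rel_tol) {
  n <- length(isis)
  if (n < 4L) return(list(class = "aperiodic", period = NA_integer_))
  period <- NA_integer_
  for (N in seq_len(min(6L, n - 1L))) {
    i <- seq_len(n - N)
    if (all(abs(isis[i + N] - isis[i]) <= rel_tol * isis[i])) {
      period <- N
      break
    }
  }
  if (is.na(period)) return(list(class = "aperiodic", period = NA_integer_))
  # reduce to the fundamental period via distinct-value count
  if (period == 1L) return(list(class = "one_spk", period = 1L))
  list(class = sprintf("periodic_%d", period), period = period)
}

#' @export
print.vn_iteration <- function(x, ...) {
  cat(sprintf("<vn_iteration> mu=%g class=%s period=%s rate=%.1f spk/s%s\n",
              x$mu, x$class, x$period,
              x$rate_mean, if (x$failed) " [failed]" else ""))
  invisible(x)
}

#' Diagnostic per-segment voltage densities for a stalled trajectory
#'
#' Occupancy densities of the three below-tangency segments: reset-to-stall
#' (proportional to 1/F), the stall itself (concentrated at the mid-segment
#' voltage), and vertex-to-threshold (1/F under the anchored line), combined
#' with weights proportional to the segment durations. Diagnostic only; the
#' iterative algorithm does not consume these.
#'
#' @param mu bias current (uA/cm^2), below the tangency point.
#' @param x_r,C_r gating reset values.
#' @param p a \code{vn_parameters} object.
#' @param n grid points.
#' @return List of \code{vn_density} objects (\code{seg1}, \code{seg_star},
#'   \code{seg2}, \code{combined}) plus the \code{weights}.
#' @export
segment_density_case2 <- function(mu, x_r, C_r, p, n = 2000L) {
  th <- theory_intervals(mu, x_r, C_r, p)
  if (th$branch != "case2") {
    stop("bias is above the tangency point; no stalled segments")
  }
  line <- adaptation_line(x_r, C_r, p)
  V1 <- seq(p$Vreset, th$Vstar, length.out = n)
  d1 <- 1 / pmax(theory_F(V1, mu, line, p), p$eps / 100)
  seg1 <- structure(list(support = V1, density = d1 / .trapz(V1, d1),
                         norm = th$I1), class = "vn_density")
  # the stall segment sits near the midpoint between V* and the vertex
  V_bar <- (th$Vstar + p$V2) / 2
  half_width <- max(abs(p$V2 - th$Vstar) / 20, 0.25)
  Vs <- seq(V_bar - half_width, V_bar + half_width, length.out = 101L)
  ds <- rep(1, 101L)
  seg_star <- structure(list(support = Vs, density = ds / .trapz(Vs, ds),
                             norm = th$I_star), class = "vn_density")
  line2 <- list(W0 = mu - p$eps - (p$gCa * th$x_end^2 +
                                     p$gKCa * th$C_end /
                                     (p$Kd + th$C_end)) * p$V2,
                Wm = p$gCa * th$x_end^2 +
                  p$gKCa * th$C_end / (p$Kd + th$C_end))
  V2g <- seq(p$V2, p$Vth, length.out = n)
  d2 <- 1 / pmax(theory_F(V2g, mu, line2, p), p$eps / 100)
  seg2 <- structure(list(support = V2g, density = d2 / .trapz(V2g, d2),
                         norm = th$I2), class = "vn_density")
  w <- c(th$I1, th$I_star, th$I2)
  w <- w / sum(w)
  lo <- p$Vreset; hi <- p$Vth
  V <- seq(lo, hi, length.out = n)
  mix <- function(s) {
    y <- stats::approx(s$support, s$density, V, yleft = 0, yright = 0,
                       rule = 1)$y
    y[is.na(y)] <- 0
    y
  }
  dc <- w[1] * mix(seg1) + w[2] * mix(seg_star) + w[3] * mix(seg2)
  combined <- structure(list(support = V, density = dc / .trapz(V, dc),
                             norm = sum(th$I1, th$I_star, th$I2)),
                        class = "vn_density")
  list(seg1 = seg1, seg_star = seg_star, seg2 = seg2, combined = combined,
       weights = w)
}
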