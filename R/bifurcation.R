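#' Reduced steady-state flow of the conductance-based model
#'
#' The voltage equation with every gating variable substituted by its
#' steady-state value: \code{H1(V, ninf(V), xinf(V), Cinf(V))}. Its zeros are
#' the fixed points of the full 4-variable system. The bias current enters
#' additively, so increasing \code{mu} translates the curve upward.
#'
#' @param V membrane voltage (mV); vectorized.
#' @param mu bias current (uA/cm^2).
#' @param p a \code{vn_parameters} object.
#' @return Net current (uA/cm^2).
#' @export
h1_reduced <- function(V, mu, p) {
  n <- ninf(V, p)
  x <- xinf(V, p)
  C <- calcium_steady_state(V, x, p, warn = FALSE)
  mu - p$gL * (V - p$VL) -
    p$gNa * minf(V, p)^3 * (1 - n) * (V - p$VNa) -
    p$gK * n^4 * (V - p$VK) -
    p$gCa * x^2 * (V - p$VCa) -
    p$gKCa * C / (p$Kd + C) * (V - p$VK)
}

#' Reduced steady-state flow of the QIF model
#'
#' The QIF voltage equation with \code{x} and \code{C} at steady state:
#' \code{mu + g2 (V - V2)^2 - ICa(V, xinf(V)) - IKCa(V, Cinf(V))}. Shares its
#' subthreshold zero structure with \code{\link{h1_reduced}} by construction.
#'
#' @inheritParams h1_reduced
#' @return Net current (uA/cm^2).
#' @export
f1_reduced <- function(V, mu, p) {
  x <- xinf(V, p)
  C <- calcium_steady_state(V, x, p, warn = FALSE)
  mu + p$g2 * (V - p$V2)^2 -
    p$gCa * x^2 * (V - p$VCa) -
    p$gKCa * C / (p$Kd + C) * (V - p$VK)
}

#' Find fixed points of the reduced flow
#'
#' Scans a dense voltage grid for sign changes of \code{\link{h1_reduced}}
#' (\code{model = "hh"}) or \code{\link{f1_reduced}} (\code{model = "qif"}),
#' refines each bracketed root by bisection to a residual below \code{tol},
#' deduplicates roots closer than 1e-6 mV, and attaches eigenvalues and
#' stability from the analytic Jacobian.
#'
#' @param model \code{"hh"} or \code{"qif"}.
#' @param mu bias current (uA/cm^2).
#' @param p a \code{vn_parameters} object.
#' @param V_window voltage interval to scan (mV); default
#'   \code{c(VK + 1, VCa - 1)}.
#' @param grid_dV scan grid spacing (mV).
#' @param tol residual tolerance for root refinement.
#' @return A data frame of class \code{vn_fixed_points} with columns \code{V},
#'   the steady-state gating values, \code{residual}, \code{stable},
#'   \code{max_re} (largest eigenvalue real part), \code{marginal}
#'   (|max_re| < 1e-9) and \code{mu}; eigenvalues in
#'   \code{attr(, "eigenvalues")} (one complex vector per root).
#' @export
find_fixed_points <- function(model = c("hh", "qif"), mu, p,
                              V_window = NULL, grid_dV = 0.01, tol = 1e-9) {
  model <- match.arg(model)
  if (is.null(V_window)) V_window <- c(p$VK + 1, p$VCa - 1)
  stopifnot(length(V_window) == 2L, all(is.finite(V_window)))
  fun <- if (model == "hh") h1_reduced else f1_reduced
  Vs <- seq(V_window[1], V_window[2], by = grid_dV)
  fv <- fun(Vs, mu, p)
  if (abs(fv[1]) < tol || abs(fv[length(fv)]) < tol) {
    warning("root at the edge of the scan window; widen V_window")
  }
  sgn <- sign(fv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(idx, function(i) {
    lo <- Vs[i]; hi <- Vs[i + 1]
    for (k in 1:200) {
      mid <- (lo + hi) / 2
      fm <- fun(mid, mu, p)
      if (abs(fm) < tol || (hi - lo) < 1e-14) return(mid)
      if (sign(fm) == sign(fun(lo, mu, p))) lo <- mid else hi <- mid
    }
    mid
  }, numeric(1))
  # grid points that are themselves (numerically) roots
  exact <- Vs[abs(fv) < tol]
  roots <- sort(c(roots, exact))
  if (length(roots) > 1L) {
    roots <- roots[c(TRUE, diff(roots) > 1e-6)]
  }
  recs <- lapply(roots, function(Vr) fixed_point_record(model, Vr, mu, p))
  out <- do.call(rbind, lapply(recs, `[[`, "row"))
  if (is.null(out)) {
    out <- data.frame(V = numeric(0), n = numeric(0), x = numeric(0),
                      C = numeric(0), residual = numeric(0),
                      stable = logical(0), max_re = numeric(0),
                      marginal = logical(0), mu = numeric(0))
  }
  attr(out, "eigenvalues") <- lapply(recs, `[[`, "eigenvalues")
  class(out) <- c("vn_fixed_points", class(out))
  out
}

fixed_point_record <- function(model, V, mu, p) {
  x <- xinf(V, p)
  C <- calcium_steady_state(V, x, p, warn = FALSE)
  n <- if (model == "hh") ninf(V, p) else NA_real_
  state <- if (model == "hh") c(V = V, n = n, x = x, C = C)
           else c(V = V, x = x, C = C)
  J <- jacobian_matrix(model, state, mu, p)
  ev <- eigen(J, only.values = TRUE)$values
  max_re <- max(Re(ev))
  resid <- if (model == "hh") h1_reduced(V, mu, p) else f1_reduced(V, mu, p)
  list(row = data.frame(V = V, n = n, x = x, C = C, residual = resid,
                        stable = max_re < 0, max_re = max_re,
                        marginal = abs(max_re) < 1e-9, mu = mu),
       eigenvalues = ev)
}

#' Analytic Jacobian of the model flow
#'
#' Partial derivatives of the 4-variable (HH) or 3-variable (QIF) vector field
#' at a given state, with the structural zeros of the gating cascade (n and x
#' do not sense each other; C senses only V and x).
#'
#' @param model \code{"hh"} or \code{"qif"}.
#' @param state named state vector (\code{V, n, x, C} or \code{V, x, C}).
#' @param mu bias current (uA/cm^2; does not enter the Jacobian, kept for
#'   interface symmetry).
#' @param p a \code{vn_parameters} object.
#' @return A 4x4 or 3x3 numeric matrix.
#' @export
jacobian_matrix <- function(model = c("hh", "qif"), state, mu, p) {
  model <- match.arg(model)
  V <- state[["V"]]; x <- state[["x"]]; C <- state[["C"]]
  m <- minf(V, p)
  mp <- 2 * p$a_m * m * (1 - m)
  xi <- xinf(V, p)
  xip <- 2 * p$a_x * xi * (1 - xi)
  dIKCa_dC <- p$gKCa * p$Kd / (C + p$Kd)^2 * (V - p$VK)
  dICa_dx <- 2 * p$gCa * x * (V - p$VCa)
  # dC/dt = (Cinf(V,x) - C)/tau_C with Cinf = -KR gCa x^2 (V - VCa)
  dH4_dV <- -p$KR * p$gCa * x^2 / p$tau_C
  dH4_dx <- -2 * p$KR * p$gCa * x * (V - p$VCa) / p$tau_C
  dH4_dC <- -1 / p$tau_C
  if (model == "hh") {
    n <- state[["n"]]
    ni <- ninf(V, p)
    nip <- 2 * p$a_n * ni * (1 - ni)
    dINa_dV <- p$gNa * (1 - n) * (3 * m^2 * mp * (V - p$VNa) + m^3)
    dH1_dV <- -(dINa_dV + p$gK * n^4 + p$gL + p$gCa * x^2 +
                  p$gKCa * C / (C + p$Kd)) / p$Cm
    dH1_dn <- (p$gNa * m^3 * (V - p$VNa) - 4 * p$gK * n^3 * (V - p$VK)) / p$Cm
    dH1_dx <- -dICa_dx / p$Cm
    dH1_dC <- -dIKCa_dC / p$Cm
    matrix(c(dH1_dV, dH1_dn, dH1_dx, dH1_dC,
             nip / p$tau_n, -1 / p$tau_n, 0, 0,
             xip / p$tau_x, 0, -1 / p$tau_x, 0,
             dH4_dV, 0, dH4_dx, dH4_dC),
           nrow = 4, byrow = TRUE,
           dimnames = list(c("V", "n", "x", "C"), c("V", "n", "x", "C")))
  } else {
    dF1_dV <- (2 * p$g2 * (V - p$V2) - p$gCa * x^2 -
                 p$gKCa * C / (C + p$Kd)) / p$Cm
    dF1_dx <- -dICa_dx / p$Cm
    dF1_dC <- -dIKCa_dC / p$Cm
    matrix(c(dF1_dV, dF1_dx, dF1_dC,
             xip / p$tau_x, -1 / p$tau_x, 0,
             dH4_dV, dH4_dx, dH4_dC),
           nrow = 3, byrow = TRUE,
           dimnames = list(c("V", "x", "C"), c("V", "x", "C")))
  }
}

#' Bifurcation diagram over a bias-current sweep
#'
#' For each bias current: the fixed points of the reduced flow with their
#' stability, plus (optionally) the voltage extremes of the spiking limit
#' cycle from simulation. The spiking onset is classified as a saddle-node
#' bifurcation if the stable low-voltage fixed point annihilates with the
#' middle one at onset, or as a Hopf bifurcation if it loses stability through
#' a complex eigenvalue pair while all three fixed points persist (the
#' remaining unstable pair then annihilates at a higher bias, reported as
#' \code{annihilation_mu}).
#'
#' @param model \code{"hh"} or \code{"qif"}.
#' @param p a \code{vn_parameters} object.
#' @param mu_grid sorted bias currents (uA/cm^2).
#' @param simulate also simulate at each bias to extract limit-cycle voltage
#'   min/max/mean (over the post-transient part of the trace).
#' @param duration,dt simulation settings when \code{simulate = TRUE}.
#' @param transient initial stretch discarded before taking extremes (ms).
#' @return A \code{vn_bifurcation} object: list with \code{fixed_points}
#'   (row-bound \code{\link{find_fixed_points}} output), \code{limit_cycle}
#'   (per-mu data frame), \code{onset_type}, \code{onset_mu},
#'   \code{annihilation_mu} (NA when onset is a saddle-node), \code{model}.
#' @export
bifurcation_diagram <- function(model = c("hh", "qif"), p, mu_grid,
                                simulate = TRUE, duration = 2000, dt = 0.01,
                                transient = 500) {
  model <- match.arg(model)
  stopifnot(!is.unsorted(mu_grid))
  fps <- lapply(mu_grid, function(mu)
    find_fixed_points(model, mu, p,
                      V_window = c(p$VK + 1, if (model == "hh") p$VCa - 1
                                   else p$Vth + 5)))
  fp_all <- do.call(rbind, lapply(fps, as.data.frame))

  # Track the lowest-voltage fixed point: stability loss and annihilation.
  low_stable <- vapply(fps, function(f)
    if (nrow(f)) f$stable[which.min(f$V)] else NA, logical(1))
  n_roots <- vapply(fps, nrow, integer(1))
  has_low_pair <- n_roots >= 3L | (n_roots >= 2L & !vapply(fps, function(f)
    if (nrow(f)) any(f$stable) else FALSE, logical(1)))

  # Stability-loss bias (Hopf candidate): refine by bisection in mu.
  hopf_mu <- NA_real_
  i <- which(low_stable[-length(low_stable)] & !low_stable[-1] &
               n_roots[-1] >= 3L)
  if (length(i)) {
    hopf_mu <- .bisect_mu(function(mu) {
      f <- find_fixed_points(model, mu, p)
      if (!nrow(f)) return(-1)
      if (f$stable[which.min(f$V)]) 1 else -1
    }, mu_grid[i[1]], mu_grid[i[1] + 1])
  }
  # Fold of the two lowest fixed points: root count drops below 3.
  fold_mu <- NA_real_
  j <- which(n_roots[-length(n_roots)] >= 3L & n_roots[-1] < 3L)
  if (length(j)) {
    fold_mu <- .bisect_mu(function(mu) {
      if (nrow(find_fixed_points(model, mu, p)) >= 3L) 1 else -1
    }, mu_grid[j[1]], mu_grid[j[1] + 1])
  }
  if (!is.na(hopf_mu) && (is.na(fold_mu) || hopf_mu < fold_mu)) {
    onset_type <- "hopf"; onset_mu <- hopf_mu; annih <- fold_mu
  } else {
    onset_type <- "saddle_node"; onset_mu <- fold_mu; annih <- NA_real_
  }

  lc <- NULL
  if (simulate) {
    lc <- do.call(rbind, lapply(mu_grid, function(mu) {
      tr <- if (model == "hh") {
        simulate_hh(p, mu, duration, dt, record = TRUE, thin = 10L)
      } else {
        simulate_qif(p, mu, duration, dt, record = TRUE, thin = 10L)
      }
      keep <- tr$times >= transient
      V <- tr$states[keep, "V"]
      spiking <- sum(tr$spike_times >= transient) >= 2
      data.frame(mu = mu, spiking = spiking,
                 V_min = if (spiking) min(V) else NA_real_,
                 V_max = if (spiking) max(V) else NA_real_,
                 V_mean = if (spiking) mean(V) else NA_real_)
    }))
  }
  structure(list(fixed_points = fp_all, limit_cycle = lc,
                 onset_type = onset_type, onset_mu = onset_mu,
                 annihilation_mu = annih, model = model, mu_grid = mu_grid),
            class = "vn_bifurcation")
}

.bisect_mu <- function(f, lo, hi, iter = 40L) {
  flo <- f(lo)
  for (k in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) == flo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' @export
print.vn_bifurcation <- function(x, ...) {
  cat(sprintf("<vn_bifurcation> model=%s  %d bias values\n",
              x$model, length(x$mu_grid)))
  cat(sprintf("  onset: %s at mu = %.4g\n", x$onset_type, x$onset_mu))
  if (!is.na(x$annihilation_mu)) {
    cat(sprintf("  unstable-pair annihilation at mu = %.4g\n",
                x$annihilation_mu))
  }
  invisible(x)
}

#' Serialize a bifurcation diagram
#'
#' @param bd a \code{vn_bifurcation} object.
#' @param json_file,csv_file output paths (either may be NULL).
#' @return Invisibly, the list that was serialized.
#' @export
write_bifurcation <- function(bd, json_file = NULL, csv_file = NULL) {
  stopifnot(inherits(bd, "vn_bifurcation"))
  obj <- list(model = bd$model, onset_type = bd$onset_type,
              onset_mu = bd$onset_mu, annihilation_mu = bd$annihilation_mu,
              fixed_points = bd$fixed_points, limit_cycle = bd$limit_cycle)
  if (!is.null(json_file)) {
    jsonlite::write_json(obj, json_file, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(csv_file)) {
    utils::write.csv(bd$fixed_points, csv_file, row.names = FALSE)
  }
  invisible(obj)
}
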