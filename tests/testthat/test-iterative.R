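test_that("subthreshold density is the normalized reciprocal flow", {
  p <- default_parameters(gCa = 0.2, reset_mode = "fixed_reset")
  ms <- mu_star(p)
  mu <- ms + 3
  d <- subthreshold_density(mu, p$x_reset, p$C_reset, p)
  # integrates to one
  expect_equal(sum(diff(d$support) *
                     (d$density[-1] + d$density[-length(d$density)]) / 2),
               1, tolerance = 1e-6)
  # its normalization constant is the closed-form interval
  line <- adaptation_line(p$x_reset, p$C_reset, p)
  expect_lt(abs(d$norm - interval_I0(mu, line, p)) /
              interval_I0(mu, line, p), 1e-8)
  # proportional to 1/F pointwise
  mid <- length(d$support) %/% 2
  ratio <- d$density[mid] * theory_F(d$support[mid], mu, line, p)
  ratio2 <- d$density[10] * theory_F(d$support[10], mu, line, p)
  expect_equal(ratio, ratio2, tolerance = 1e-9)
  # misuse below the tangency raises
  expect_error(subthreshold_density(ms - 1, p$x_reset, p$C_reset, p),
               "tangency")
})

test_that("spike density is the waveform's time-occupancy measure", {
  p <- default_parameters()
  d <- spike_density(p, n = 2001L)
  expect_equal(sum(diff(d$support) *
                     (d$density[-1] + d$density[-length(d$density)]) / 2),
               1, tolerance = 1e-6)
  # Monte-Carlo oracle: sample uniform times, map through the waveform
  set.seed(11)
  ts <- runif(2e5, 0, p$tau_r)
  Vs <- spike_waveform_value(ts, p)
  br <- seq(p$Vreset, p$Vmax, length.out = 41L)
  emp <- as.numeric(table(cut(Vs, br))) / length(Vs)
  thr <- vapply(seq_len(40L), function(i) {
    sel <- d$support >= br[i] & d$support <= br[i + 1]
    sum(diff(d$support[sel]) *
          (d$density[sel][-1] + d$density[sel][-sum(sel)]) / 2)
  }, numeric(1))
  expect_lt(max(abs(cumsum(emp) - cumsum(thr))), 0.01)  # KS-style distance
  # rising-branch occupancy: uniform density of weight t1/tau_r over
  # [Vth, Vmax] stacked on the falling-branch background
  i_hi <- which(d$support > p$Vth + 1 & d$support < p$Vmax - 1)
  expect_lt(diff(range(d$density[i_hi])), 1e-9)
})

test_that("combined density collapses to its components in the weight limits", {
  p <- default_parameters(gCa = 0.2, reset_mode = "fixed_reset")
  ms <- mu_star(p)
  p0 <- subthreshold_density(ms + 3, p$x_reset, p$C_reset, p)
  ps <- spike_density(p)
  # refractory weight -> 0: the mixture is the subthreshold density
  c0 <- combined_density(p0, ps, I0 = 10, tau_r = 1e-12)
  at <- function(d, v) approx(d$support, d$density, v)$y
  for (v in c(-60, -45, -30)) {
    expect_equal(at(c0, v), at(p0, v), tolerance = 1e-4)
  }
  # drift interval -> 0: the mixture is the spike density
  c1 <- combined_density(p0, ps, I0 = 1e-12, tau_r = p$tau_r)
  for (v in c(0, 15, 25)) {
    expect_equal(at(c1, v), at(ps, v), tolerance = 1e-4)
  }
  # with consistent supports the mixture needs no renormalization
  cc <- combined_density(p0, ps, I0 = 8, tau_r = 3)
  mass <- sum(diff(cc$support) *
                (cc$density[-1] + cc$density[-length(cc$density)]) / 2)
  expect_equal(mass, 1, tolerance = 1e-6)
})

test_that("self-consistent means sift point masses and stay in range", {
  p <- default_parameters(gCa = 0.2)
  # near-point-mass density at V0
  V0 <- -40
  V <- seq(V0 - 0.01, V0 + 0.01, length.out = 101L)
  dens <- structure(list(support = V, density = rep(1 / 0.02, 101L),
                         norm = 1), class = "vn_density")
  m <- self_consistent_means(dens, p)
  expect_equal(unname(m["x"]),
               steady_state_activation(V0, p$a_x, p$Vhalf_x),
               tolerance = 1e-4)
  expect_equal(unname(m["C"]),
               calcium_steady_state(
                 V0, steady_state_activation(V0, p$a_x, p$Vhalf_x), p),
               tolerance = 1e-3)
  # grid refinement stability on a broad density
  ms <- mu_star(p, 0.1, p$C_reset)
  d1 <- subthreshold_density(ms + 3, 0.1, p$C_reset, p, n = 2000L)
  d2 <- subthreshold_density(ms + 3, 0.1, p$C_reset, p, n = 8000L)
  m1 <- self_consistent_means(d1, p)
  m2 <- self_consistent_means(d2, p)
  expect_lt(max(abs(m1 - m2)), 1e-6)
  expect_true(m1["x"] >= 0 && m1["x"] <= 1)
})

test_that("iteration without calcium settles immediately to a single interval", {
  p <- default_parameters(gCa = 0, gKCa = 0)
  it <- iterate_qif_theory(8, p, n_transient = 5L, n_keep = 10L)
  expect_false(it$failed)
  expect_equal(it$class, "one_spk")
  expect_true(all(it$log$branch == "case1"))
  expect_lt(diff(range(it$isis)), 1e-10)
  # successive resets identical once at the fixed point
  tail_log <- utils::tail(it$log, 5)
  expect_lt(diff(range(tail_log$x_out)), 1e-8)
  expect_lt(diff(range(tail_log$C_out)), 1e-8)
})

test_that("iteration is deterministic and logs both branch types", {
  p <- default_parameters(gCa = 0.2)
  a <- iterate_qif_theory(20.5, p, n_transient = 5L, n_keep = 10L)
  b <- iterate_qif_theory(20.5, p, n_transient = 5L, n_keep = 10L)
  expect_identical(a$log, b$log)
  expect_setequal(unique(a$log$branch), c("case1", "case2"))
  expect_false(a$failed)
  expect_true(all(a$log$x_out >= 0 & a$log$x_out <= 1))
  expect_true(all(a$log$C_out >= 0))
})

test_that("iterative prediction matches the simulated rate at low bias", {
  p <- default_parameters(gCa = 0.2)
  it <- iterate_qif_theory(5, p)
  expect_equal(it$class, "one_spk")
  tr <- quick_qif(p, 5, 4000)
  sim_rate <- 1000 / mean(isi_sequence(tr$spike_times)[-(1:10)])
  expect_lt(abs(it$rate_mean - sim_rate) / sim_rate, 0.25)
})

test_that("segment densities are weighted by their interval lengths", {
  p <- default_parameters(gCa = 0.2, reset_mode = "fixed_reset")
  ms <- mu_star(p)
  sd2 <- segment_density_case2(ms - 1.5, p$x_reset, p$C_reset, p)
  th <- theory_intervals(ms - 1.5, p$x_reset, p$C_reset, p)
  expect_equal(sd2$weights,
               c(th$I1, th$I_star, th$I2) / (th$I1 + th$I_star + th$I2),
               tolerance = 1e-9)
  expect_equal(sum(sd2$weights), 1)
  # the stall segment concentrates near the mid-segment voltage
  V_bar <- (th$Vstar + p$V2) / 2
  peak <- sd2$seg_star$support[which.max(sd2$seg_star$density)]
  expect_lt(abs(peak - V_bar), 1)
  # the combination integrates to one
  cc <- sd2$combined
  mass <- sum(diff(cc$support) *
                (cc$density[-1] + cc$density[-length(cc$density)]) / 2)
  expect_equal(mass, 1, tolerance = 1e-6)
  # misuse above the tangency raises
  expect_error(segment_density_case2(ms + 1, p$x_reset, p$C_reset, p),
               "tangency")
})
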