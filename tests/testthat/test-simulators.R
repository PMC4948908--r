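test_that("model right-hand sides vanish where they must", {
  p <- default_parameters(gCa = 0.6)
  # at a fixed point of the reduced flow all four derivatives vanish
  fps <- find_fixed_points("hh", 5, p, c(p$Vreset, p$Vth))
  expect_gte(nrow(fps), 1L)
  st <- c(V = fps$V[1], n = fps$n[1], x = fps$x[1], C = fps$C[1])
  expect_true(all(abs(hh_rhs(st, 5, p)) < 1e-9))
  # gate at steady state: no gate flux
  st2 <- c(V = -40, n = steady_state_activation(-40, p$a_n, p$Vhalf_n),
           x = 0.2, C = 1)
  expect_equal(unname(hh_rhs(st2, 0, p)["n"]), 0)
  # closed calcium pathway: no calcium flux
  p0 <- default_parameters(gCa = 0)
  expect_equal(unname(hh_rhs(c(V = -40, n = 0.2, x = 0.3, C = 0), 0, p0)["C"]),
               0)
  # QIF parabola vertex with silent calcium: no voltage flux
  expect_equal(unname(qif_rhs(c(V = p0$V2, x = 0, C = 0), 0,
                              default_parameters(gCa = 0, gKCa = 0))["V"]), 0)
  # psi is symmetric about the vertex
  pq <- default_parameters(gCa = 0, gKCa = 0)
  dv1 <- qif_rhs(c(V = pq$V2 + 10, x = 0, C = 0), 0, pq)["V"]
  dv2 <- qif_rhs(c(V = pq$V2 - 10, x = 0, C = 0), 0, pq)["V"]
  expect_equal(dv1, dv2)
})

test_that("fixed-step integration is bit-reproducible", {
  p <- default_parameters(gCa = 0.6)
  a <- simulate_hh(p, 19, 200, 0.01)
  b <- simulate_hh(p, 19, 200, 0.01)
  expect_identical(a$states, b$states)
  expect_identical(a$spike_times, b$spike_times)
  qa <- simulate_qif(p, 15, 200, 0.01)
  qb <- simulate_qif(p, 15, 200, 0.01)
  expect_identical(qa$states, qb$states)
})

test_that("subthreshold bias relaxes to the stable fixed point", {
  # bias below the onset of the coexisting limit cycle
  p <- default_parameters(gCa = 0.6)
  fps <- find_fixed_points("hh", 3, p, c(p$Vreset, p$Vth))
  stable <- fps[fps$stable, ]
  expect_equal(nrow(stable), 1L)
  tr <- simulate_hh(p, 3, 2000, 0.01)
  tail_V <- utils::tail(tr$states[, "V"], 1)
  expect_equal(unname(tail_V), stable$V, tolerance = 1e-5)
  expect_lte(length(tr$spike_times), 2L)  # at most a transient spike or two
})

test_that("spike detection interpolates upward crossings and merges doubles", {
  # synthetic sawtooth crossing 0 mV five times
  t <- seq(0, 50, by = 0.01)
  V <- 20 * (t %% 10) / 10 - 10
  tr <- structure(list(times = t, states = cbind(V = V), spike_times = NULL,
                       mu = 0, dt = 0.01, model = "hh",
                       integrator_id = "synthetic"), class = "vn_trace")
  s <- detect_spikes(tr, vdetect = 0)
  expect_length(s, 5L)
  expect_equal(s, c(5, 15, 25, 35, 45), tolerance = 1e-6)
  # constant subthreshold trace: nothing detected
  tr$states <- cbind(V = rep(-60, length(t)))
  expect_length(detect_spikes(tr, 0), 0L)
  # chattering crossings inside the guard merge to one
  V2 <- rep(-10, length(t))
  V2[t > 10 & t < 10.5] <- 10
  V2[t > 10.6 & t < 11] <- 10
  tr$states <- cbind(V = V2)
  expect_length(detect_spikes(tr, 0, guard = 1), 1L)
})

test_that("fixed-step and adaptive integrators agree on interspike intervals", {
  p <- default_parameters(gCa = 0)
  a <- simulate_hh(p, 10, 400, 0.01)
  b <- simulate_hh(p, 10, 400, 0.01, integrator = "lsoda")
  ia <- isi_sequence(a$spike_times)
  ib <- isi_sequence(b$spike_times)
  n <- min(length(ia), length(ib))
  expect_gt(n, 10)
  expect_lt(max(abs(ia[2:n] - ib[2:n]) / ia[2:n]), 1e-3)
})

test_that("halving the step moves spike times by less than the step", {
  p <- default_parameters(gCa = 0.6)
  a <- simulate_hh(p, 19, 300, 0.01, record = FALSE)
  b <- simulate_hh(p, 19, 300, 0.005, record = FALSE)
  n <- min(length(a$spike_times), length(b$spike_times))
  expect_gt(n, 5)
  expect_lt(max(abs(a$spike_times[1:n] - b$spike_times[1:n])), 0.01)
})

test_that("integration blow-up raises rather than returning garbage", {
  p <- default_parameters()
  expect_error(simulate_hh(p, 1e7, 10, 0.5), "blew up")
})

test_that("artificial spike waveform hits its three anchor points", {
  p <- default_parameters()
  expect_equal(spike_waveform_value(0, p), p$Vth)
  expect_equal(spike_waveform_value(p$t1, p), p$Vmax)
  expect_equal(spike_waveform_value(p$tau_r, p), p$Vreset)
  expect_error(spike_waveform_value(p$tau_r + 1, p), "tau_r")
  # piecewise linear between anchors
  tmid <- p$t1 / 2
  expect_equal(spike_waveform_value(tmid, p), (p$Vth + p$Vmax) / 2)
})

test_that("gating integration through the spike is convergent and state-dependent", {
  p <- default_parameters(gCa = 0.2)
  e1 <- integrate_gating_through_spike(0.2, 1, p, dt = 0.01)
  e2 <- integrate_gating_through_spike(0.2, 1, p, dt = 0.005)
  expect_lt(max(abs(e1[c("x_end", "C_end")] - e2[c("x_end", "C_end")])), 1e-6)
  # increments shrink with the refractory window
  pshort <- default_parameters(gCa = 0.2, t1 = 0.02, tau_r = 0.1)
  eshort <- integrate_gating_through_spike(0.2, 1, pshort)
  expect_lt(abs(eshort[["dx"]]), abs(e1[["dx"]]) / 5)
  expect_lt(abs(eshort[["dC"]]), abs(e1[["dC"]]) / 5)
  # state dependence distinguishes the waveform rule from the fixed rules
  e3 <- integrate_gating_through_spike(0.05, 0.2, p)
  expect_false(isTRUE(all.equal(e1[["dx"]], e3[["dx"]])))
})

test_that("QIF reset rules implement their taxonomy", {
  p <- default_parameters(gCa = 0.2)
  # fixed_reset: every post-spike gating state identical
  tr <- quick_qif(p, 8, 1500,
                  reset_rule = reset_rule("fixed_reset", x_reset = 0.1))
  expect_gt(length(tr$spike_times), 10)
  expect_equal(diff(range(tr$x_at_reset)), 0)
  expect_equal(diff(range(tr$C_at_reset)), 0)
  expect_equal(count_distinct_isis(isi_sequence(tr$spike_times),
                                   n_discard = 5L), 1L)
  # spike_waveform: gating resets vary with the state at threshold
  tr2 <- quick_qif(p, 12, 1500)
  expect_gt(diff(range(tr2$x_at_reset)), 0)
  # reset rule objects validate their required fields
  expect_error(reset_rule("fixed_delta"), "dx")
  expect_error(reset_rule("fixed_reset"), "x_reset")
})

test_that("plain QIF limit recovers the integrate-and-fire interval", {
  # gCa = 0, vanishing quadratic drive: ISI -> (Vth - Vreset)/mu
  p <- default_parameters(gCa = 0, gKCa = 0, g2 = 1e-9, tau_r = 0.2,
                          t1 = 0.1)
  mu <- 20
  tr <- simulate_qif(p, mu, 400, 0.001, record = FALSE)
  isis <- isi_sequence(tr$spike_times)
  expect_gt(length(isis), 10)
  expect_equal(mean(isis), (p$Vth - p$Vreset) / mu + p$tau_r,
               tolerance = 1e-3)
})
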