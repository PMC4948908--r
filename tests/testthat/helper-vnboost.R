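# Shared helpers: short simulations and canonical parameter sets used across
# the test files. All fixtures are generated in code; nothing is read from
# disk except what a test itself writes to a tempdir.

quick_hh <- function(p, mu, duration = 2000, dt = 0.01, ...) {
  simulate_hh(p, mu, duration, dt, record = FALSE, ...)
}

quick_qif <- function(p, mu, duration = 2000, dt = 0.01, ...) {
  simulate_qif(p, mu, duration, dt, record = FALSE, ...)
}

hh_pattern <- function(p, mu, duration = 3000) {
  tr <- quick_hh(p, mu, duration)
  classify_firing_pattern(isi_sequence(tr$spike_times))
}

# deterministic pseudo-random admissible theory parameter draw
random_theory_params <- function(i) {
  set.seed(1000 + i)
  p <- default_parameters(gCa = runif(1, 0.05, 0.4),
                          g2 = runif(1, 0.05, 0.2),
                          V2 = runif(1, -55, -45),
                          gKCa = runif(1, 1, 3),
                          Kd = runif(1, 2, 8),
                          reset_mode = "fixed_reset",
                          x_reset = runif(1, 0.05, 0.3))
  p
}
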