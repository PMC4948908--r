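# vnboost

Vestibular nucleus (VN) neurons recorded *in vivo* show a **boosting
nonlinearity** in their input–output tuning curves: the firing rate grows
with a shallow slope at low input currents and a markedly steeper slope at
high ones, the opposite of the usual saturating shape. `vnboost` implements
a modelling suite that reproduces and explains this effect with a
conductance-based (Hodgkin–Huxley-type) VN neuron model whose calcium and
calcium-activated potassium currents generate a bidirectional
afterhyperpolarization (AHP), and with its reduction to a generalized
adaptive quadratic integrate-and-fire (QIF) model.

The package is aimed at computational neuroscientists who want to simulate
these models, map their bifurcation structure, and evaluate the analytic
firing-rate and gain theory that links the AHP, the period-adding bursting
window, and the boosting nonlinearity.

## Models

**Conductance-based model** (4 variables `V, n, x, C`):

    Cm dV/dt = mu - I_Na - I_K - I_leak - I_Ca - I_KCa
       dn/dt = (n_inf(V) - n)/tau_n
       dx/dt = (x_inf(V) - x)/tau_x
       dC/dt = (C_inf(V,x) - C)/tau_C,      C_inf = -K_R I_Ca

with `I_Na = g_Na m_inf^3 (1-n)(V - V_Na)`, `I_K = g_K n^4 (V - V_K)`,
`I_Ca = g_Ca x^2 (V - V_Ca)`, `I_KCa = g_KCa C/(C + K_d) (V - V_K)` and
logistic steady-state activations `z_inf(V) = 1/(1 + exp(-2a(V - V_1/2)))`.
The calcium conductance `g_Ca` is the bifurcation parameter of the study.

**Adaptive QIF reduction** (3 variables `V, x, C`): the spike generator is
replaced by `psi(V) = g2 (V - V2)^2` plus a threshold/reset boundary
condition, with three gating reset rules — an artificial piecewise-linear
spike waveform (physiological, state-dependent), fixed increments
`(dx, dC)`, or fixed values `(x_reset, C_reset)`.

**Slow-gating theory** (fixed resets): freezing `x, C` at their reset values
turns the calcium currents into a linear adaptation current
`W(V) = W0 + Wm V`. The bias `mu*` at which the drive parabola
`mu + psi(V)` detaches from `W(V)` splits the interspike interval into a
single arctan integral (above) or a three-segment decomposition
`I1 + I* + I2` (below), giving the closed-form rate
`R(mu) = 1/(I1 + I* + I2 + tau_r)` or `1/(I0 + tau_r)` and gain
approximations that scale as `(mu* - mu)^-2` from below and
`(mu - mu*)^-1/2` from above — the gain peaks at `mu*`.

**Iterative self-consistency**: when the resets are spike-generated, the
algorithm alternates between a drift branch (voltage occupancy density plus
mean-gating closure) and a stalled branch (gating decay through the
artificial spike) until the ISI sequence settles; the retained sequence is
classified through its return map.

## Worked example

```r
library(vnboost)

p <- default_parameters(gCa = 0.6)          # packaged VN parameter set
tr <- simulate_hh(p, mu = 19, duration = 6000, dt = 0.01)
cls <- classify_firing_pattern(isi_sequence(tr$spike_times))
cls$pattern
#> [1] "burst_2"
round(cls$distinct_isis, 2)
#> [1]  7.97 42.06

mu_star(default_parameters(gCa = 0.2, reset_mode = "fixed_reset"))
#> [1] 4.152493
```

At `gCa = 0.6` and bias 19 the model fires two-interval bursts: a short
(8.0 ms) and a long (42.1 ms) interval alternate, the first step of the
period-adding sequence (tonic at bias 18, two-interval bursts at 19,
three-interval bursts at 22). `mu_star` is the tangency bias of the
slow-gating theory — the bias at which the gain of the fixed-reset QIF
peaks.

Sweeps are reproducible through configs (see `inst/configs/`) or the thin
CLI:

```sh
Rscript inst/cli/vnboost.R fi --model hh --gca 0,0.2,0.4,0.6 --out sweeps/
Rscript inst/cli/vnboost.R theory --config theory-rate-gain --out sweeps/
```

## Parameter provenance

Only part of the biophysical constants of the source VN model are printed in
its description (`tau_n, tau_x, tau_C, g2, V2, Vmax, t1, tau_r, eps`); the
rest are reconstructed here and calibrated against the printed anchors
(quadratic curvature `g2 = 0.1` near -50 mV, onset near zero bias without
calcium, the period-adding window anchors, the subthreshold fixed-point
counts). `parameter_provenance(default_parameters())` lists every value with
its status, and the methods vignette (`vignettes/methods.Rmd`) documents the
calibration, the numerical choices and the known limitations.
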