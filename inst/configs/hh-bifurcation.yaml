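# fixed points, stability, onset type and limit-cycle extremes vs bias
sweep: bifurcation
model: hh
mu_min: 0
mu_max: 26
mu_step: 0.5
gca_values: [0.0, 0.2, 0.4, 0.6]
duration: 2000
dt: 0.01
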