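sweep: bifurcation
model: qif
mu_min: 0
mu_max: 26
mu_step: 0.5
gca_values: [0.0, 0.05, 0.1, 0.2]
duration: 2000
dt: 0.01
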