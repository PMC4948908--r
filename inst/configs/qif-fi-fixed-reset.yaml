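# f-I with fixed gating reset values (the analytically tractable variant)
sweep: fi
model: qif
mu_min: 0
mu_max: 30
mu_step: 0.5
gca_values: [0.0, 0.05, 0.1, 0.15, 0.2]
duration: 4000
dt: 0.01
reset_mode: fixed_reset
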