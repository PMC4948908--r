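# normalized differences between analytic and simulated gain
sweep: theory
model: qif
mu_min: 0.5
mu_max: 12
mu_step: 0.25
gca_values: [0.2]
reset_mode: fixed_reset
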