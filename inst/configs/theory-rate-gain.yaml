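# analytic interval decomposition, firing rate and gain over a bias sweep
sweep: theory
model: qif
mu_min: 0.5
mu_max: 12
mu_step: 0.25
gca_values: [0.05, 0.1, 0.15, 0.2]
reset_mode: fixed_reset
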