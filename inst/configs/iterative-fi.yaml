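# self-consistent iterative rate prediction for spike-generated resets
sweep: iterative
model: qif
mu_min: 2
mu_max: 24
mu_step: 1
gca_values: [0.0, 0.05, 0.1, 0.2]
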