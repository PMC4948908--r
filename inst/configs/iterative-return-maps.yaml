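# return-map classification of the iterative ISI sequences
sweep: iterative
model: qif
mu_grid: [6, 10, 14, 18, 20.5, 22]
gca_values: [0.2]
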