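# ISI return maps across the QIF bursting window (gCa = 0.2)
sweep: return_map
model: qif
mu_grid: [10, 12, 14, 20.5]
gca_values: [0.2]
duration: 6000
dt: 0.01
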