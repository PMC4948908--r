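# ISI return maps across the period-adding burst window (gCa = 0.6)
sweep: return_map
model: hh
mu_grid: [18, 19, 22, 22.5]
gca_values: [0.6]
duration: 6000
dt: 0.01
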