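# f-I curves of the conductance-based model across calcium conductances
sweep: fi
model: hh
mu_min: 0
mu_max: 30
mu_step: 0.5
gca_values: [0.0, 0.2, 0.4, 0.6]
duration: 4000
dt: 0.01
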