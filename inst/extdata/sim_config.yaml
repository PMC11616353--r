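n_probands: 200000
p_female: 0.5
p_maternal: 0.5
baseline_rate: 0.01
rr_autosomal: 2
rr_x: 1.25
rr_y: 1
seed: 20240614
n_reps: 200
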