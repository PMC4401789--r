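simulate: TRUE
seed: 1
k: 10
filter_min_frac: 0.6
min_overlap: 3
dims: 3
max_iter: 1000
rho_threshold: 0.5
cfn_mode: inclusive
n_random: 70
p_cut: 0.01
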