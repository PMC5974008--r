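# Example benchmark configuration for `contourreg benchmark`.
# Omitted fields take the documented defaults.
fractions: [0.43, 0.23, 0.07]
levels: [0]
algorithms: [R, SM+R1, SM+R2]
runs: 50
seed: 1
noise_sigma: 0
d_ransac: 5
n_features: 150
k: 5
subdiv: 4
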