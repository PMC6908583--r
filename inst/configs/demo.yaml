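n_train: 16
n_test: 8
tile_size: 64
sigma_preset: sigma_2
metric: mse
epochs: 1
batch_size: 1
learning_rate: 0.002
n_hpf: 2
hpf_size: 160
n_windows: 10
seed: 7
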