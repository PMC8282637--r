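# Example dashsim run configuration.
# Missing keys take package defaults (f = 0.3, P = 5, pad_factor = 2,
# sample_model = layer, ...).
seed: 42
algorithm: dash
n_slm: 16
n_scat: 32
i0: 1000
P: 5
iterations: 9
out_dir: dashsim-out
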