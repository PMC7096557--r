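seed: 42
n_perm: 100
min_nuclei: 10
min_module_size: 10
top_n_specific: 30
alpha: 0.1
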