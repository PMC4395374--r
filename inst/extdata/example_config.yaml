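# Example pipeline configuration (see read_run_config() for the schema).
n_te: 9
n_multiplies: [3, 6]
hpf_n_points: 64
seed: 1
phantom:
  noise_sigma: 0.03
  n_coils: 4
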