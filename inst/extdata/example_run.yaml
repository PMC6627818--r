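# Example pipeline configuration for read_run_config()/run_pipeline().
# A quoted "n" avoids YAML 1.1 reading the bare key as a boolean.
seed: 1
arm: cold
"n": {northern: 10, southern: 11}
sample_interval: 5
hold_hours: [20, 5, 18]
noise_sd: 0.25
r2_min: 0.95
min_obs: 10
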