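# Scaled-down run configuration for read_run_config(); omitted keys take the
# package defaults (13-stage forebrain design, E-window 4e-60..4e-23, a_min 10).
seed: 7
bait_len: 100
sim:
  read_length: 101
  library_size: 20000
  replicates: 3
filter:
  evalue_low: 4.0e-60
  evalue_high: 4.0e-23
  max_hits: 20000
  a_min: 10
stats:
  alpha: 0.05
  posthoc_adjustment: none
profiles:
  - stage_label: E14
    target_fraction: 0.04
    skip_fraction: 0.10
  - stage_label: E19
    target_fraction: 0.0304
    skip_fraction: 0.45
  - stage_label: P7
    target_fraction: 0.0248
    skip_fraction: 0.10
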