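# full-pipeline configuration over the packaged synthetic cohort
cohort_config: synthetic_cohort.yaml
seed: 42
preprocess:
  calibrate: true
  baseline: true
bucket:
  range_low: 1.0
  range_high: 12.0
  width: 0.01
  exclusions:
  - {low: 4.75, high: 5.06}
  - {low: 3.16, high: 3.45}
  - {low: -0.05, high: 0.05}
cluster:
  k: 23
assign:
  delta_tol: 0.03
  j_tol: 1.0
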