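# Demo run: a small synthetic cohort with discovery-scale methylation
# moments and effect sizes, pushed through the full pipeline including
# the read-count / coverage-file layer.
seed: 20100
outdir: methbp_demo_out
tau: 0.1
B: 499
qc:
  conversion_threshold: 0.98
  min_mean_coverage: 20
simulate:
  n_samples: 600
  read_counts: true
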