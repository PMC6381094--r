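# Desk-scale demonstration scenario for the screening pipeline:
# 100 barcoded reagents, six donors in three cohorts, triplicate
# reagent-pool baselines, five 50x spike-ins per sorted sample.
out_dir: pmhcscreen_demo
seed: 1
n_barcodes: 100
n_binders: 100
depth: 10000
n_baseline: 3
error_rate: 0.002
n_nt1: 2
n_dq_pos: 2
n_dq_neg: 2
spikes_per_donor: 5
fold_enrichment: 50
max_mismatch: 1
baseline_jitter_sd: 0.25
enrichment:
  trim_m: 0.30
  trim_a: 0.05
  dispersion: auto
  p_threshold: 0.001
  min_clonal: 100
  pseudocount: 0.5
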