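# Demo run: a small synthetic cohort through the full pipeline.
schema_version: 1
seed: 7
out: roiconn_demo_out
synth:
  n_nodes: 36
  n_timepoints: 150
  groups:
    placebo: 2
    CBD: 2
  sessions: [chronic, washout]
  module_sizes: [12, 12, 12]
  within_module_corr: 0.3
  between_module_corr: 0.05
  effect_multipliers:
    CBD:
      washout: 1.4
preprocess:
  z_cut: 4
  low_hz: 0.01
  high_hz: 0.1
connectome:
  bootstrap: false
graphm:
  q_iter: 3
  node_density: 0.16
roistats:
  measure: volume_mm3
  test: kruskal
  q: 0.2
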