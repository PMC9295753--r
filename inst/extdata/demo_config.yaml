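# Demo configuration for the end-to-end pipeline (synthetic data).
# Every key mirrors an argument of run_config(); omitted keys take the
# documented defaults and are echoed into the run manifest.
seed: 1
synthetic: true
n_short: 1000
n_long: 1000
percentile: 0.01
min_distance: 1000000
span: 0.6
n_boot: 50
slack_bp: 10000
threshold_nm: 150
fc_cut: 1
p_cut: 0.05
n_cells_wt: 2190
n_cells_mt: 520
contact_prob_wt: 0.4
contact_prob_mt: 0.05
conserved_frac: 0.3
concordant_frac: 0.92
depth: 5000000
n_sites: 300
effect_size: 2
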