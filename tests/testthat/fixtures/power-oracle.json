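{
  "scenario": "scan_power",
  "n_genes": 2000,
  "n_target": 20,
  "enrichment_factor": 10,
  "background_rate_per_bp": 0.001,
  "flank_pair_bp": 2000,
  "alpha": 0.01,
  "oracle_reps": 5000,
  "recall_mean": 19.9948,
  "recall_q01": 20,
  "fp_mean": 8.9602,
  "fp_q99": 17
}
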