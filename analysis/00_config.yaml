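# Shared configuration of the analysis workflow (validated by
# facmri::pipeline_config). The grid is scaled down from the full
# 96 x 128 study matrix for a fast narrative run.
seed: 1
out_dir: results
cohort:
  n_a: 15
  n_b: 23
phantom:
  matrix_size: [48, 64]
  sat_thickness: 6
  fascia_offset: 3
  snr: 50
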