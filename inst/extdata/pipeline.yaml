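# Standard synthetic study configuration for the full pipeline.
# Scalar fields here override the defaults built by
# default_pipeline_config(); everything omitted keeps its default.
rng_seed: 1
simulate:
  n_case: 10
  n_control: 10
  coverage: 20
  read_length: 75
  n_rate: 0.005
  host_read_count: 300
classifier:
  epochs: 4
assembly:
  seed_threshold: 0.46
  min_overlap: 24
  max_contig_length: 2000
annotation:
  e_max_nt: 0.01
  e_max_prot: 1.0e-5
  backend: builtin
contaminants: []
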