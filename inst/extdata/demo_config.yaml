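# Demo pipeline configuration: a small simulated genome with three planted
# Stowaway-like families, mined, classified and genotyped end to end.
seed: 11
simulate:
  genome_length: 100000
  at_fraction: 0.65
  n_families: 3
  copies_per_family: 8
  divergence: 0.05
  indel_rate: 0.002
mine:
  terminal_motif: CTCCCT
  min_tir: 13
  max_len: 600
  require_tsd: true
classify:
  min_identity: 0.80
  min_coverage: 0.80
  min_length: 80
copy_number:
  clone_size: 10000
  n_clones: 100
  method: both
genotype:
  n_accessions: 30
  flank_length: 300
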