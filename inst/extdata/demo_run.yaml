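simulation:
  seed: 7
  n_snps_per_chromosome: 400
  n_chromosomes: 10
  n_target_individuals: 16
  n_reference_individuals: 12
  missing_rate: 0.1
  relative_plan:
  - degree: 1
    cemeteries: [S, S]
  - degree: 2
    cemeteries: [R, S]
analysis:
  maxdis: 0.3
  min_overlap: 500
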