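base_config:
  n_membrane: 240
  n_nucleus: 80
  n_filaments: 19
  beads_per_filament: 20
  r_cell: 12.0
  r_nucleus: 4.0
  u3: 3.0
  kappa00: 10.0
  kappa_nuc: 100.0
  kappa_fil: 100.0
  kappa_bend_mem: 5.0
  kappa_bend_fil: 20.0
  kappa_area: 50.0
  sigma: 1.0
  eps_rep: 1.0
  kT: 1.0
  gamma: 1.0
  dt: 0.0002
  n_steps: 20000
  save_every: 1250
  seed: 1
  protrusive_count: 1
  grow_interval: 0.07
  grow_max: 45
u3_values:
- 3.0
- 30.0
kappa00_values: 500.0
replicates: 5
root_seed: 1
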