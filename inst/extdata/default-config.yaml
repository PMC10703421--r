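# Default simulation configuration: calibrated parameter values, the
# aggregate-expression (mitoFluc) evaluation laws and biased fission on.
# Any field may be omitted; omitted fields take these defaults.
parameters:
  unit_mito_volume: 0.12      # um^3, mean fragment volume of the fusion-null strain
  mother_cell_volume: 54.04   # um^3
  total_mito_volume: 6.56     # um^3
  bud_mito_volume: 1.83       # um^3
  dump_occupancy: 0.122       # fraction of mitochondrial volume in DUMPs
  dt_sim: 0.1                 # s, simulation timestep
  dt_expt: 10                 # s, experimental movie frame interval
  t_equil: 1800               # s, WT equilibration phase
  t_eval: 5400                # s, evaluation phase
  prob_model: linear          # per-step probability: linear (rate*dt) or exact
  diffusion_floor: 1.0e-12    # um^2/s, lower clamp on diffusion laws
profiles:
  wt:
    fission:   {slope: 1.28e-3,  intercept: -1.67e-3}
    fusion:    {slope: -3.72e-4, intercept: 8.04e-3}
    diffusion: {slope: -3.90e-5, intercept: 9.50e-4}
  dump_neg:
    fission:   {slope: 1.57e-3,  intercept: -5.48e-4}
    fusion:    {slope: -7.93e-4, intercept: 1.19e-2}
    diffusion: {slope: 1.74e-4,  intercept: 1.32e-3}
  dump_pos:
    fission:   {slope: 1.19e-3,  intercept: -1.33e-3}
    fusion:    {slope: -1.59e-4, intercept: 7.15e-3}
    diffusion: {slope: -4.10e-5, intercept: 9.57e-4}
configuration:
  fission_fusion: mitofluc    # mitofluc (DUMP-/DUMP+ laws) or wt
  diffusion: mitofluc
  placement_mode: biased      # random | biased | adjacent
  biased_fraction: 1.0
seeding:
  mode: clustered             # clustered | singlets
  # cluster_count: 1          # fixed cluster count; omit to draw from the
  # distribution below (synthetic placeholder: truncated geometric, mean 1.5 clusters)
  cluster_count_distribution: [0.66758, 0.22253, 0.07418, 0.02473, 0.00824, 0.00275]
run:
  n_reps: 1
  base_seed: 1
  snapshot_dt: 10
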