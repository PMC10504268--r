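# Default demonstration configuration for the chained Min-size pipeline.
# Reduced resolution so the whole chain runs in about a minute; the analysis
# scripts under analysis/ use fuller settings.
model: {}   # wild-type Min kinetics (package defaults)
scan:
  ratio_multipliers: [1.0, 1.04, 1.08]
  lengths: [2.5, 3.0, 3.5, 4.0, 4.5, 5.0, 5.5, 6.0]
  criterion: argmin_avg_occupancy
  t_end: 400
  dx: 0.1
  use_sim_map: false
occupancy:
  window_w: 0.5
  threshold_mode: fraction_of_spatial_mean
  theta: 0.5
  burn_in: 200
induction:
  minE_initial: 1
  minE_final: 3
  t_c: 50
  t_s: 25
  unit: min
growth:
  alpha: 0.027726
  tau: 18.75
  lopt_a: 2.4
  lopt_b: 0.6
synth:
  n_lineages: 10
  n_generations: 12
  alpha_cv: 0.07
  tau_cv: 0.07
  division_fraction_sd: 0.035
  lstable_cv: 0.05
  induction_start_gen: 6
  ring_plateau: 1000
  intensity_noise_sd: 20
  background_mean: 100
analysis:
  threshold_fraction: 0.65
  g_max: 10
run:
  seed: 1
  out_dir: results
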