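# Baseline study conditions: 2 x 2 mm field of view, 250-um capillary grid,
# sub-50-um seed nodule, day-18 injection of 100-nm alpha=1e12 nanoparticles.
# Any subset of keys may be given; omitted keys take these defaults.
schema: 1
seed: 1
grid:
  n_cells: 96
  domain_mm: 2.0
  length_scale_mm: 0.1
vessels:
  spacing_mm: 0.25
  radius: 1.0e-05
  p_in: 500.0
  p_out: 0.0
  viscosity: 0.003
tumor:
  seed_radius_mm: 0.04
  dt_days: 0.1
  lambda_M: 1.0
  lambda_A: 0.25
  lambda_N: 0.35
  lambda_effect: 0.0
  mu: 1.0
  chi_E: 0.0
  sigma_H: 0.5
  sigma_N: 0.3
oxygen:
  D_sigma: 100.0
  lambda_ev: 80000.0
  lambda_tissue: 1100.0
  lambda_tumor: 10000.0
  q_s: 3000.0
  lambda_necrotic: 2000.0
  HD: 0.45
  h_min: 0.25
  k_pi: 1.0
  ifp_length_mm: 0.1
angiogenesis:
  D_taf: 0.8
  lambda_taf: 20.0
  s_taf: 20.0
  D_tip: 1.0
  chi_taf: 40.0
  chi_ecm: 0.0
  taf_threshold: 0.05
  sprout_rate: 1.0
  branch_rate: 0.5
  max_tips: 40.0
  neovessel_hematocrit_frac: 0.5
np:
  d: 1.0e-07
  alpha_neo: 1.0e+12
  beta: 0.0001
  gamma: 10000.0
  delta1: 0.45
  delta2: 1.57
  d_ref: 1.0e-07
  injection_duration_s: 3600.0
  dt_s: 60.0
drug:
  D_G: 0.022
  D_ref: 4.0
  half_life_h: 6.0
  release_time_ref_h: 12.0
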