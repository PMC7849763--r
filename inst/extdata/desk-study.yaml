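# Desk-scale digital thorax study: the default configuration, written out in
# full so every block and key is visible. Values shown equal the defaults.
phantom:
  grid_shape: [64, 64, 48]
  voxel_mm: [2, 2, 2]
  n_phases: 10
  period_s: 4.0
  diaphragm_si_mm: 20.0
  chest_ap_mm: 12.0
  heart_si_mm: 10.0
recon:
  lambda: 1.0
  n_iter: 25
  lambda_decay: 1.0
  tv_weight: 0.0
tv:
  n_iter: 8
  tv_weight: 0.3
  tv_steps: 4
demons:
  levels: 3
  iterations: [50, 50, 30]
  sigma_fluid: 1.5
  sigma_diffusion: 1.0
bilateral:
  sigma_x: 3.0
  sigma_mu: 0.03
  sigma_v: 2.5
dvf:
  regularizer: bilateral
  max_iter: 10
  proj_interval: 10
pipeline:
  outer: 2
  views_per_phase: 20
  seed: 1
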