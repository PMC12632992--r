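# Reference parameter set for the stoichiometric spindle model.
# Units: um, s, pN throughout; drag coefficients in pN s/um.
mt_params:
  n_mt: 5000        # microtubules per aster
  v_g: 1            # growth velocity (um/s)
motor_params:
  rho: 0.12         # cortical motor density (1/um^2)
  r: 1.5            # motor size / capture radius (um)
  kappa: 0.05       # detachment rate (1/s)
  f0: 5             # per-motor force (pN)
drag_params:
  eta: 450          # pole drag (pN s/um)
  nu: 50            # pole-chromosome viscous coupling (pN s/um)
chromosome_law:
  c_f: 6.2          # final chromosome separation (um)
  tau_c: 29         # separation time constant (s)
stages:
  - {stage: 2,  cell_radius_um: 23,  initial_d_pp_um: 13,  lambda_s: 0.038}
  - {stage: 4,  cell_radius_um: 18,  initial_d_pp_um: 11.2, lambda_s: 0.086}
  - {stage: 8,  cell_radius_um: 14,  initial_d_pp_um: 9,   lambda_s: 0.164}
  - {stage: 16, cell_radius_um: 11,  initial_d_pp_um: 7.5, lambda_s: 0.332}
  - {stage: 32, cell_radius_um: 9,   initial_d_pp_um: 6.4, lambda_s: 0.615}
  - {stage: 64, cell_radius_um: 7.3, initial_d_pp_um: 5.4, lambda_s: 0.945}
sim:
  dt: 0.05          # integration step (s)
  t_end: 300        # simulated duration (s)
  n_patches: 2000   # surface mesh size
  sample_every: 10.3  # output sampling interval (s)
  seed: 1
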