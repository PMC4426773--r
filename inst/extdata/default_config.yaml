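material:
  F_hat: 0.581
  eps_N0: 0.165
  rho_s: 1500.0
  'N': 100
  m: 15
  l: 6.5e-10
  R_i: 0.000375
  hydrolysate_factor: 2.32
  D_F_inf: 1.12e-09
grid:
  n_fibre: 100
  n_hydro: 250
conditions:
  T_C: 110.0
  C_H: 51.0
  t_end_min: 360.0
solver:
  rtol: 1.0e-07
  atol: 1.0e-10
constants:
  k_B: 1.38e-23
  R: 8.314
composition:
  glucan: 0.438
  xylan: 0.202
  arabinan: 0.033
  lignin: 0.275
  acetyl: 0.025
  ash: 0.021
sample:
  dry_mass_g: 4.68
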