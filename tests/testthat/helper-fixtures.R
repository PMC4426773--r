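# Shared fixtures: the published per-temperature calibration results and
# small model configurations sized for fast, exact property checks.

table2 <- list(
  T_K = c(383.15, 398.15, 413.15),
  k_a = c(2.0630e-4, 5.7028e-4, 1.6667e-2),
  k_b = c(1.5434e-5, 5.7128e-5, 1.2914e-4),
  k_d = c(7.9618e-9, 5.3401e-8, 2.6999e-7),
  alpha = c(0.32016, 0.17809, 0.05211),
  k0 = c(k_a = 1.6467e22, k_b = 8.9850e7, k_d = 9.9506e12),
  Ea = c(k_a = 1.9129e5, k_b = 9.3422e4, k_d = 1.54675e5),
  alpha_A = 4.1820e9, alpha_b = 6.0514e-2)

params_110 <- kinetic_params(k_a = 2.0630e-4, k_b = 1.5434e-5,
                             k_d = 7.9618e-9, alpha = 0.32016)

# small but fully two-region geometry for solver behaviour tests
tiny_geom <- function(...) {
  material_geometry(N = 12, m = 4, n_fibre = 8, n_hydro = 6, ...)
}

# geometry for calibration recovery studies (kept deliberately small so a
# single objective evaluation is ~0.1 s)
fit_geom <- function() {
  material_geometry(N = 12, m = 4, n_fibre = 6, n_hydro = 3)
}

fit_cond <- function() {
  conditions(T_K = 383.15, t_end = 360 * 60,
             output_times = seq(300, 360 * 60, length.out = 40))
}

# random non-negative state on a given geometry, reproducible
random_state <- function(geom, seed = 42) {
  set.seed(seed)
  n_tot <- geom$n_fibre + geom$n_hydro
  state_field(
    geom,
    phi_F = runif(n_tot, 0, 1),
    phi_aq = matrix(runif(geom$m * n_tot, 0, 10), geom$m, n_tot),
    phi_solid = matrix(runif((geom$N - geom$m) * geom$n_fibre, 0, 2),
                       geom$N - geom$m, geom$n_fibre),
    alpha = 0.1)
}
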