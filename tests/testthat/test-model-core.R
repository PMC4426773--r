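test_that("breakage kernel weights and mass closure", {
  expect_equal(breakage_kernel(1, 2), 0.5)          # single bond in a dimer
  expect_equal(breakage_kernel(2, 3), 1 / 3)
  # brute-force closure: every parent's fragments carry exactly its mass
  for (j in c(2, 3, 10, 57)) {
    expect_equal(sum(2 * breakage_kernel(seq_len(j - 1), j)), 1)
  }
  expect_error(breakage_kernel(3, 3), "i < j")
  expect_error(breakage_kernel(0, 5), "i < j")
})

test_that("Arrhenius evaluation", {
  expect_equal(arrhenius_rate(arrhenius_fit(3.7, 0), 298.15), 3.7)
  fit <- arrhenius_fit(k0 = 9.9506e12, Ea = 1.54675e5)
  # global-law evaluation lands near the independently fitted 125 degC value
  expect_equal(arrhenius_rate(fit, 398.15), 5.3401e-8, tolerance = 0.10)
  expect_gt(arrhenius_rate(fit, 413.15), arrhenius_rate(fit, 383.15))
  expect_error(arrhenius_rate(fit, -5), "positive")
  expect_error(arrhenius_fit(-1, 10), "k0")
})

test_that("hard-to-hydrolyse temperature law", {
  law <- alpha_law(A = 4.1820e9, b = 6.0514e-2)
  expect_equal(alpha_of_T(law, 383.15), 0.3563, tolerance = 1e-3)
  expect_lt(alpha_of_T(law, 2000), 1e-30)          # vanishes at high T
  expect_error(alpha_of_T(law, 300), "below the validity window")
  expect_error(alpha_of_T(law, 0), "positive")
  # b -> 0 degeneracy: effectively temperature-independent alpha
  expect_equal(alpha_of_T(alpha_law(A = 0.5, b = 1e-15), c(300, 500)),
               c(0.5, 0.5), tolerance = 1e-10)
})

test_that("effective acid concentration", {
  expect_equal(effective_acid(1, 51), 51)
  expect_equal(effective_acid(0.254, 51), 12.954)
  expect_equal(effective_acid(0, 1234), 0)
  expect_error(effective_acid(1.2, 51), "\\[0, 1\\]")
})

test_that("Stokes-Einstein diffusivities with tortuosity", {
  geom <- material_geometry()
  # tortuosity factor is identity at unit porosity, eps^3 otherwise
  D1 <- diffusivity(1, 383.15, eps_v = 1, geom)
  expect_equal(diffusivity(1, 383.15, eps_v = 0.5, geom), D1 / 8)
  # R_h ~ sqrt(i): the tetramer diffuses at half the monomer rate
  expect_equal(diffusivity(4, 383.15, eps_v = 1, geom), D1 / 2)
  expect_equal(diffusivity("furfural", 383.15, eps_v = 1, geom), 1.12e-9)
  expect_error(diffusivity(1, 383.15, eps_v = -0.1), "\\[0, 1\\]")
  # viscosity correlation sanity: ~0.89 mPa s at 25 degC
  expect_equal(water_viscosity(298.15), 8.9e-4, tolerance = 0.02)
})

test_that("porosity closure", {
  geom <- material_geometry()
  full <- matrix(0, geom$N - geom$m, 4)
  full[geom$N - geom$m, ] <- geom$eps_N0 * geom$rho_s
  expect_equal(porosity(full, geom, alpha = 0), rep(0.254, 4))
  expect_equal(porosity(numeric(geom$N - geom$m), geom, alpha = 0), 0.419)
  expect_equal(porosity(numeric(geom$N - geom$m), geom, alpha = 0.32016),
               1 - (0.581 + 0.32016 * 0.165))
  expect_error(porosity(-full, geom), "non-negative")
  # over-filled node is an invariant violation, not a silent clamp
  expect_error(porosity(full * 4, geom), "porosity <= 0")
})

test_that("initial monodisperse state", {
  geom <- tiny_geom()
  cond <- conditions(T_K = 383.15, t_end = 60)
  alpha <- 0.32016
  st <- initial_state(geom, cond, kinetic_params(1e-4, 1e-5, 1e-8, alpha))
  expect_equal(unique(st$phi_solid[geom$N - geom$m, ]),
               (1 - alpha) * geom$eps_N0 * geom$rho_s)
  expect_true(all(st$phi_solid[-(geom$N - geom$m), ] == 0))
  expect_true(all(st$phi_aq == 0))
  expect_true(all(st$phi_F == 0))
  # porosity is uniform at the initial value, independent of alpha
  expect_equal(unique(st$eps_v[seq_len(geom$n_fibre)]),
               1 - geom$F_hat - geom$eps_N0)
  expect_true(all(st$eps_v[-seq_len(geom$n_fibre)] == 1))
  # fully unreactive limit: no reactive material anywhere
  st1 <- initial_state(geom, cond, kinetic_params(1e-4, 1e-5, 1e-8, 1))
  expect_true(all(st1$phi_solid == 0))
})

test_that("temperature laws reproduce the per-temperature calibration with the scatter the data allow", {
  # the three per-temperature fits are not collinear on the Arrhenius plot:
  # k_b and k_d scatter within 15%, but k_a (which jumps 29x between the
  # two upper temperatures) deviates up to a factor ~2.3, and alpha at the
  # middle temperature by ~19%
  for (nm in c("k_b", "k_d")) {
    fit <- fit_arrhenius(table2$T_K, table2[[nm]])
    expect_equal(arrhenius_rate(fit, table2$T_K), table2[[nm]],
                 tolerance = 0.15)
  }
  fit_a <- fit_arrhenius(table2$T_K, table2$k_a)
  ratio <- arrhenius_rate(fit_a, table2$T_K) / table2$k_a
  expect_true(all(ratio > 1 / 2.5 & ratio < 2.5))
  law <- fit_alpha_law(table2$T_K, table2$alpha)
  expect_equal(alpha_of_T(law, table2$T_K), table2$alpha, tolerance = 0.25)
})

test_that("type validation catches inconsistent configurations", {
  expect_error(material_geometry(F_hat = 0.9, eps_N0 = 0.2), "\\(0, 1\\)")
  expect_error(material_geometry(m = 100, N = 100), "1 < m < N")
  expect_error(material_geometry(n_fibre = 2), ">= 3")
  expect_error(conditions(T_K = 383, t_end = 60,
                          output_times = c(30, 20)), "increasing")
  expect_error(conditions(T_K = 383, t_end = 60, output_times = c(30, 90)),
               "within")
  expect_error(kinetic_params(-1, 0, 0), "non-negative")
  expect_error(kinetic_params(1e-4, 1e-5, 1e-8, alpha = 1.2), "\\[0, 1\\]")
})
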