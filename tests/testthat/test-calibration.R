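test_that("spline interpolation of model curves", {
  geom <- tiny_geom()
  cond <- conditions(T_K = 383.15, t_end = 3600,
                     output_times = seq(0, 3600, by = 360))
  traj <- simulate_hydrolysis(geom, cond,
                              kinetic_params(2e-4, 1.5e-5, 0, 0.1))
  ys <- yields(traj, dp = 1:2)
  # interpolation identity at the simulation output times
  at_nodes <- model_at_times(ys, ys$time_min[ys$species == "X1"])
  expect_equal(at_nodes$yield_pct[at_nodes$species == "X1"],
               ys$yield_pct[ys$species == "X1"], tolerance = 1e-12)
  # monotone segment: interpolant stays within the bracketing values
  x1 <- ys[ys$species == "X1", ]
  seg <- sort(x1$time_min)[1:2]
  mid <- model_at_times(ys, mean(seg))
  v <- mid$yield_pct[mid$species == "X1"]
  lo <- min(x1$yield_pct[x1$time_min %in% seg])
  hi <- max(x1$yield_pct[x1$time_min %in% seg])
  expect_true(v >= lo - 1e-9 && v <= hi + 1e-9)
  expect_error(model_at_times(ys, 100 + max(x1$time_min)),
               "outside the simulated horizon")
})

test_that("objective definition and error handling", {
  geom <- fit_geom()
  cond <- fit_cond()
  params <- kinetic_params(2.063e-4, 1.5434e-5, 7.9618e-9, 0.32016)
  obs <- generate_experiment(params, geom, cond,
                             sample_times_min = c(30, 120, 300),
                             noise = noise_model(0, 0),
                             species = c("furfural", "X1", "X2"))
  res <- hydrolysis_objective(
    c(k_a = params$k_a, k_b = params$k_b, k_d = params$k_d,
      alpha = params$alpha), obs, geom, cond)
  expect_equal(attr(res, "Phi"), 0, tolerance = 1e-16)
  expect_equal(as.numeric(res), numeric(nrow(obs)), tolerance = 1e-9)

  # a single observation off by 2 yield-% contributes Phi = 4
  obs2 <- obs
  obs2$yield_pct[5] <- obs2$yield_pct[5] + 2
  res2 <- hydrolysis_objective(
    c(k_a = params$k_a, k_b = params$k_b, k_d = params$k_d,
      alpha = params$alpha), obs2, geom, cond)
  expect_equal(attr(res2, "Phi"), 4, tolerance = 1e-9)

  bad <- obs
  bad$species[1] <- "glucose"
  expect_error(hydrolysis_objective(c(k_a = 1e-4), bad, geom, cond),
               "unknown species")
  expect_error(hydrolysis_objective(c(k_q = 1), obs, geom, cond),
               "unknown parameter")
})

test_that("all-zero observations drive rates to the lower bound", {
  geom <- fit_geom()
  cond <- conditions(T_K = 383.15, t_end = 7200,
                     output_times = seq(300, 7200, length.out = 15))
  obs <- data.frame(species = "X1",
                    time_min = c(10, 30, 60, 120),
                    yield_pct = 0)
  fit <- fit_kinetics(obs, geom, cond, free = "k_a",
                      start = c(k_a = 1e-4),
                      base_params = kinetic_params(0, 0, 0))
  expect_lt(fit$par[["k_a"]], 1e-9)
  expect_equal(fit$Phi, sum(fit$residuals^2))
})

test_that("closed-form Arrhenius regression", {
  # exact 2-point log-linear identity
  f0 <- arrhenius_fit(k0 = 5e10, Ea = 1.2e5)
  T2 <- c(390, 420)
  rec <- fit_arrhenius(T2, arrhenius_rate(f0, T2))
  expect_equal(rec$k0, f0$k0, tolerance = 1e-10)
  expect_equal(rec$Ea, f0$Ea, tolerance = 1e-10)

  # independent route: stats::lm on the same log-linear problem
  k <- table2$k_a
  ours <- fit_arrhenius(table2$T_K, k)
  lmfit <- stats::lm(log(k) ~ I(1 / table2$T_K))
  expect_equal(ours$Ea, -unname(coef(lmfit)[2]) * GAS_CONSTANT,
               tolerance = 1e-12)
  expect_equal(log(ours$k0), unname(coef(lmfit)[1]), tolerance = 1e-12)

  # published Arrhenius constants are reproduced from the per-temperature
  # rate table
  for (nm in c("k_a", "k_b", "k_d")) {
    fit <- fit_arrhenius(table2$T_K, table2[[nm]])
    expect_equal(fit$Ea, table2$Ea[[nm]], tolerance = 0.01)
    expect_equal(fit$k0, table2$k0[[nm]], tolerance = 0.01)
  }
  expect_error(fit_arrhenius(383, 1e-4), ">= 2")
  expect_error(fit_arrhenius(c(383, 398), c(1e-4, -1)), "positive")
})

test_that("closed-form exponential alpha regression", {
  law0 <- alpha_law(A = 2e8, b = 0.05)
  T2 <- c(385, 415)
  rec <- fit_alpha_law(T2, alpha_of_T(law0, T2))
  expect_equal(rec$A, law0$A, tolerance = 1e-10)
  expect_equal(rec$b, law0$b, tolerance = 1e-10)

  law <- fit_alpha_law(table2$T_K, table2$alpha)
  expect_equal(law$A, table2$alpha_A, tolerance = 0.01)
  expect_equal(law$b, table2$alpha_b, tolerance = 0.001)

  # permutation invariance of the least-squares fit
  perm <- c(3, 1, 2)
  law_p <- fit_alpha_law(table2$T_K[perm], table2$alpha[perm])
  expect_equal(law_p$A, law$A)
  expect_equal(law_p$b, law$b)
  expect_error(fit_alpha_law(table2$T_K, c(0.3, 0, 0.1)), "positive")
})

test_that("temperature-law prediction respects the validity window", {
  arr <- list(k_a = fit_arrhenius(table2$T_K, table2$k_a),
              k_b = fit_arrhenius(table2$T_K, table2$k_b),
              k_d = fit_arrhenius(table2$T_K, table2$k_d))
  law <- fit_alpha_law(table2$T_K, table2$alpha)
  geom <- tiny_geom()
  cond <- conditions(T_K = 383.15, t_end = 3600)
  expect_error(predict_at_temperature(arr, law, 370, geom, cond),
               "validity window")
  # alpha decreases monotonically across the calibrated range
  a <- alpha_of_T(law, seq(383.15, 443.15, by = 15))
  expect_true(all(diff(a) < 0))
})

test_that("higher temperature moves the xylose peak earlier and higher", {
  arr <- list(k_a = fit_arrhenius(table2$T_K, table2$k_a),
              k_b = fit_arrhenius(table2$T_K, table2$k_b),
              k_d = fit_arrhenius(table2$T_K, table2$k_d))
  law <- fit_alpha_law(table2$T_K, table2$alpha)
  geom <- material_geometry(N = 20, m = 5, n_fibre = 12, n_hydro = 20)
  cond155 <- conditions(T_K = 428.15, t_end = 7200,
                        output_times = seq(60, 7200, by = 120))
  y155 <- predict_at_temperature(arr, law, 428.15, geom, cond155, dp = 1,
                                 furfural = FALSE)
  x155 <- y155[y155$species == "X1", ]
  cond110 <- conditions(T_K = 383.15, t_end = 360 * 60,
                        output_times = seq(600, 360 * 60, by = 1200))
  traj110 <- simulate_hydrolysis(geom, cond110, params_110)
  x110 <- yields(traj110, dp = 1, furfural = FALSE)
  expect_gt(max(x155$yield_pct), max(x110$yield_pct))
  expect_lt(x155$time_min[which.max(x155$yield_pct)],
            x110$time_min[which.max(x110$yield_pct)])
  expect_lt(x155$time_min[which.max(x155$yield_pct)], 60)
})
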