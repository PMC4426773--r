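test_that("reaction terms: zero state, dimer kinetics, pointwise mass balance", {
  geom <- tiny_geom()
  cond <- conditions(T_K = 383.15, t_end = 60)
  params <- kinetic_params(2e-4, 1.5e-5, 8e-9, alpha = 0)
  n_tot <- geom$n_fibre + geom$n_hydro

  zero <- state_field(geom, numeric(n_tot), matrix(0, geom$m, n_tot),
                      matrix(0, geom$N - geom$m, geom$n_fibre))
  rz <- reaction_terms(zero, params, cond)
  expect_true(all(rz$phi_F == 0) && all(rz$phi_aq == 0) &&
                all(rz$phi_solid == 0))

  # only dimers present: d(phi_1)/dt = +k_b psi phi_2, d(phi_2)/dt = -same
  A <- matrix(0, geom$m, n_tot); A[2, ] <- 3.5
  dimer <- state_field(geom, numeric(n_tot), A,
                       matrix(0, geom$N - geom$m, geom$n_fibre))
  rd <- reaction_terms(dimer, params, cond)
  psi <- dimer$eps_v * cond$C_H
  expect_equal(rd$phi_aq[1, ], params$k_b * psi * 3.5)
  expect_equal(rd$phi_aq[2, ], -params$k_b * psi * 3.5)
  expect_true(all(rd$phi_aq[3:geom$m, ] == 0))
  expect_true(all(rd$phi_F == 0))

  # kernel closure + 1:1 furfural bookkeeping: species rates sum to zero
  # at every node
  st <- random_state(geom)
  r <- reaction_terms(st, params, cond)
  node_sum <- r$phi_F + colSums(r$phi_aq)
  node_sum[seq_len(geom$n_fibre)] <- node_sum[seq_len(geom$n_fibre)] +
    colSums(r$phi_solid)
  expect_equal(node_sum, numeric(length(node_sum)),
               tolerance = 1e-12 * max(abs(r$phi_aq)))
})

test_that("diffusion terms: uniform field, conservation, flux direction", {
  geom <- tiny_geom()
  cond <- conditions(T_K = 383.15, t_end = 60)
  n_tot <- geom$n_fibre + geom$n_hydro

  unif <- state_field(geom, rep(2, n_tot),
                      matrix(5, geom$m, n_tot),
                      matrix(1, geom$N - geom$m, geom$n_fibre))
  du <- diffusion_terms(unif, cond)
  expect_equal(max(abs(du$phi_F)), 0, tolerance = 1e-20)
  expect_equal(max(abs(du$phi_aq)), 0, tolerance = 1e-20)

  st <- random_state(geom)
  d <- diffusion_terms(st, cond)
  v <- st$grid$vol
  # telescoping fluxes: diffusion alone moves no mass in or out
  expect_equal(sum(d$phi_F * v), 0, tolerance = 1e-12 * sum(abs(d$phi_F) * v))
  for (i in seq_len(geom$m))
    expect_equal(sum(d$phi_aq[i, ] * v), 0,
                 tolerance = 1e-12 * max(sum(abs(d$phi_aq[i, ]) * v), 1e-30))
  expect_true(all(d$phi_solid == 0))

  # steep fibre -> hydrolysate gradient: hydrolysate side gains mass
  A <- matrix(0, geom$m, n_tot); A[1, seq_len(geom$n_fibre)] <- 10
  grad_st <- state_field(geom, numeric(n_tot), A,
                         matrix(0, geom$N - geom$m, geom$n_fibre))
  dg <- diffusion_terms(grad_st, cond)
  expect_gt(dg$phi_aq[1, geom$n_fibre + 1], 0)
  expect_lt(dg$phi_aq[1, geom$n_fibre], 0)
})

test_that("packed integrator right-hand side equals reaction + diffusion", {
  geom <- tiny_geom()
  cond <- conditions(T_K = 383.15, t_end = 60)
  params <- kinetic_params(2e-4, 1.5e-5, 8e-9, alpha = 0.1)
  st <- random_state(geom)
  layout <- xylanpbm:::make_layout(geom)
  rhs <- xylanpbm:::make_rhs(geom, st$grid, layout, params, cond,
                             solver_control())
  dy <- rhs(0, xylanpbm:::pack_state(st, layout), NULL)[[1]]
  rt <- reaction_terms(st, params, cond)
  dt <- diffusion_terms(st, cond)
  ref <- numeric(layout$n_states)
  ref[layout$iF] <- rt$phi_F + dt$phi_F
  ref[layout$iA] <- rt$phi_aq + dt$phi_aq
  ref[layout$iS] <- rt$phi_solid
  expect_equal(dy, ref, tolerance = 1e-14)
})

test_that("trajectories conserve mass and respect monotonicity", {
  geom <- tiny_geom()
  cond <- conditions(T_K = 383.15, t_end = 7200,
                     output_times = seq(0, 7200, by = 720))
  params <- kinetic_params(2.063e-4, 1.5434e-5, 5e-7, alpha = 0.2)
  traj <- simulate_hydrolysis(geom, cond, params)
  expect_equal(traj$times, cond$output_times)

  states <- lapply(seq_along(traj$times), get_state, traj = traj)
  masses <- vapply(states, total_mass, numeric(1), include_unreactive = TRUE)
  expect_equal(masses / masses[1], rep(1, length(masses)), tolerance = 1e-8)

  solid <- vapply(states, function(s)
    sum(s$phi_solid %*% s$grid$vol[seq_len(geom$n_fibre)]), numeric(1))
  furf <- vapply(states, function(s) sum(s$phi_F * s$grid$vol), numeric(1))
  expect_true(all(diff(solid) <= 1e-12 * solid[1]))
  expect_true(all(diff(furf) >= -1e-12 * max(furf)))

  # porosity: bounded by the initial and final closures, non-decreasing
  eps_f <- vapply(states, function(s)
    mean(s$eps_v[seq_len(geom$n_fibre)]), numeric(1))
  expect_true(all(eps_f >= 1 - geom$F_hat - geom$eps_N0 - 1e-10))
  expect_true(all(eps_f <= 1 - geom$F_hat - params$alpha * geom$eps_N0 + 1e-10))
  expect_true(all(diff(eps_f) >= -1e-12))
})

test_that("zero kinetics freeze the state", {
  geom <- tiny_geom()
  cond <- conditions(T_K = 383.15, t_end = 3600,
                     output_times = c(0, 1800, 3600))
  traj <- simulate_hydrolysis(geom, cond, kinetic_params(0, 0, 0, 0.3))
  expect_equal(traj$Y[3, ], traj$Y[1, ], tolerance = 1e-12)
})
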