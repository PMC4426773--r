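#' Solver control settings
#'
#' @param rtol,atol Relative and absolute integration tolerances.
#' @param maxsteps Maximum internal integrator steps between output times.
#' @param D_inf Optional constant bulk chain diffusivity (m^2 s^-1)
#'   replacing the Stokes-Einstein law (used when diffusivity is a fitted
#'   parameter); `NULL` keeps the chain-length-dependent law.
#' @param D_F_inf Optional furfural bulk diffusivity override; `NULL` uses
#'   the geometry's value.
#' @param viscosity Viscosity function of temperature (Pa s).
#' @return A list of class `solver_control`.
#' @export
solver_control <- function(rtol = 1e-7, atol = 1e-10, maxsteps = 100000L,
                           D_inf = NULL, D_F_inf = NULL,
                           viscosity = water_viscosity) {
  structure(list(rtol = rtol, atol = atol, maxsteps = as.integer(maxsteps),
                 D_inf = D_inf, D_F_inf = D_F_inf, viscosity = viscosity),
            class = "solver_control")
}

# Packed right-hand side closure over precomputed constants. Mathematically
# identical to reaction_terms() + diffusion_terms(); kept allocation-lean
# because the banded Jacobian estimation calls it O(bandwidth) times per
# Jacobian update.
make_rhs <- function(geom, grid, layout, params, cond, control) {
  m <- geom$m; N <- geom$N; n_sol <- N - m
  n_f <- geom$n_fibre; n_tot <- layout$n_tot
  iF <- layout$iF; iA <- as.vector(layout$iA); iS <- as.vector(layout$iS)
  C_H <- cond$C_H
  k_a <- params$k_a; k_b <- params$k_b; k_d <- params$k_d
  alpha <- params$alpha
  F_hat <- geom$F_hat; eps_N0 <- geom$eps_N0; rho_s <- geom$rho_s

  w_aq <- c(0, 1 / ((2:m) * ((2:m) - 1)))
  w_sol <- 1 / (((m + 1):N) * (((m + 1):N) - 1))
  UA <- suffix_sum_matrix(m)
  US <- suffix_sum_matrix(n_sol)
  i_aq <- seq_len(m)
  i_sol <- (m + 1):N
  loss_coef <- c(k_d, rep(k_b, m - 1))
  Dinf <- bulk_diffusivities(geom, cond$T_K, control$D_inf, control$D_F_inf,
                             control$viscosity)
  n <- n_tot
  inv_drf <- rep(1 / grid$dr_face, each = m + 1)
  rface <- rep(grid$r_face, each = m + 1)
  inv_vol <- rep(1 / grid$vol, each = m + 1)
  fib <- seq_len(n_f)

  function(t, y, p) {
    A <- matrix(y[iA], m, n_tot)
    S <- matrix(y[iS], n_sol, n_f)
    Ac <- pmax(A, 0); Sc <- pmax(S, 0)

    eps_v <- rep(1, n_tot)
    eps_v[fib] <- pmax(1 - (F_hat + colSums(Sc) / rho_s + alpha * eps_N0),
                       1e-12)
    psi <- eps_v * C_H

    sS <- Sc * w_sol
    SA <- UA %*% (Ac * w_aq)
    SS <- US %*% sS
    Bmat <- matrix(0, m, n_tot)
    Bmat[, fib] <- matrix(colSums(sS), m, n_f, byrow = TRUE)

    r_aq <- (2 * i_aq * (k_b * SA + k_a * Bmat) - loss_coef * Ac) *
      rep(psi, each = m)
    r_sol <- (2 * k_a * i_sol * SS - k_a * Sc) * rep(psi[fib], each = n_sol)
    r_F <- k_d * psi * Ac[1, ]

    d <- outer(Dinf, eps_v^3)
    dL <- d[, -n, drop = FALSE]; dR <- d[, -1, drop = FALSE]
    Dface <- 2 * dL * dR / (dL + dR)
    P <- rbind(y[iF], A)
    flux <- rface * Dface *
      (P[, -1, drop = FALSE] - P[, -n, drop = FALSE]) * inv_drf
    net <- (cbind(flux, 0) - cbind(0, flux)) * inv_vol

    dy <- numeric(layout$n_states)
    dy[iF] <- r_F + net[1, ]
    dy[iA] <- r_aq + net[-1, , drop = FALSE]
    dy[iS] <- r_sol
    list(dy)
  }
}

#' Integrate the fibre-hydrolysate reaction-diffusion system
#'
#' Method-of-lines solution of the coupled population-balance /
#' radial-diffusion system on the two-region cylindrical grid. The porosity
#' closure is substituted algebraically, so the system is a closed stiff
#' ODE system; it is integrated with a BDF method (`deSolve::lsode`) using
#' an internally generated banded Jacobian (node-major state ordering,
#' half-bandwidth `2N + 1`).
#'
#' @param geom A [material_geometry()].
#' @param cond A [conditions()] object; the state is reported at
#'   `cond$output_times`.
#' @param params A [kinetic_params()] object.
#' @param control A [solver_control()].
#' @param state0 Optional initial [state_field()]; defaults to the
#'   monodisperse [initial_state()].
#' @return An object of class `hydrolysis_trajectory`: times (s), packed
#'   state snapshots, and the geometry/grid/conditions/parameters of the
#'   run. Use [yields()] to extract yield curves and [get_state()] for
#'   individual snapshots.
#' @examples
#' \donttest{
#' geom <- material_geometry(N = 20, m = 5, n_fibre = 10, n_hydro = 15)
#' cond <- conditions(T_K = 383.15, t_end = 3600)
#' par <- kinetic_params(2.063e-4, 1.5434e-5, 7.9618e-9, alpha = 0.32016)
#' traj <- simulate_hydrolysis(geom, cond, par)
#' head(yields(traj, dp = 1:2))
#' }
#' @export
simulate_hydrolysis <- function(geom, cond, params,
                                control = solver_control(),
                                state0 = NULL) {
  grid <- build_grid(geom)
  layout <- make_layout(geom)
  if (is.null(state0)) state0 <- initial_state(geom, cond, params)
  y0 <- pack_state(state0, layout)
  times <- cond$output_times
  prepend0 <- times[1] > 0
  if (prepend0) times <- c(0, times)
  rhs <- make_rhs(geom, grid, layout, params, cond, control)
  bw <- min(layout$bandwidth, layout$n_states - 1L)
  out <- deSolve::lsode(y = y0, times = times, func = rhs, parms = NULL,
                        jactype = "bandint", bandup = bw, banddown = bw,
                        rtol = control$rtol, atol = control$atol,
                        maxsteps = control$maxsteps)
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop(sprintf(paste0("stiff integration failed (istate = %d); last good ",
                        "time %.6g s"), diagn[1], max(out[, 1])),
         call. = FALSE)
  if (nrow(out) < length(times))
    stop(sprintf("stiff integration stopped early at t = %.6g s",
                 max(out[, 1])), call. = FALSE)
  Y <- out[, -1, drop = FALSE]
  if (prepend0) {
    Y <- Y[-1, , drop = FALSE]
    times <- times[-1]
  }
  scale0 <- max(y0)
  worst <- min(Y)
  if (worst < -1e-8 * scale0)
    warning(sprintf(paste0("negative concentrations beyond tolerance trap: ",
                           "min = %.3e (%.1e of initial scale)"),
                    worst, abs(worst) / scale0), call. = FALSE)
  structure(list(times = times, Y = Y, geom = geom, grid = grid,
                 layout = layout, cond = cond, params = params,
                 control = control),
            class = "hydrolysis_trajectory")
}

#' @export
print.hydrolysis_trajectory <- function(x, ...) {
  cat(sprintf("<hydrolysis_trajectory> %d snapshots over %.1f min, %d states\n",
              length(x$times), max(x$times) / 60, ncol(x$Y)))
  print(x$cond)
  print(x$params)
  invisible(x)
}

#' Extract one snapshot of a trajectory as a state field
#'
#' @param traj A [simulate_hydrolysis()] trajectory.
#' @param index Snapshot index (into `traj$times`).
#' @return A [state_field()].
#' @export
get_state <- function(traj, index) {
  u <- unpack_state(traj$Y[index, ], traj$layout)
  state_field(traj$geom, pmax(u$phi_F, 0), pmax(u$phi_aq, 0),
              pmax(u$phi_solid, 0), alpha = traj$params$alpha,
              grid = traj$grid)
}

#' Yield curves from a trajectory
#'
#' Yields are percentages of the initial xylan mass (reactive plus
#' unreactive): each species' cell-weighted mass (weights `r_k dr_k`) over
#' the relevant region, divided by the initial fibre xylan mass
#' `sum_fibre r_k (phi_N(0) + alpha eps_N0 rho_s) dr_k`. Aqueous species and
#' furfural are summed over the hydrolysate nodes (interface included);
#' solid chains over the fibre nodes.
#'
#' @param traj A [simulate_hydrolysis()] trajectory.
#' @param dp Aqueous chain lengths to report (each `<= m`), as species
#'   `"X1"`, `"X2"`, ...
#' @param furfural Report furfural yield.
#' @param solid_dp Solid chain lengths to report (each in `m+1..N`), as
#'   species `"S<dp>"` in region `"fibre"`.
#' @param solid_total Report the total solid xylan remnant (`"solid_total"`).
#' @return A tidy data.frame with columns `time_min`, `species`,
#'   `yield_pct`, `region`.
#' @export
yields <- function(traj, dp = 1:6, furfural = TRUE, solid_dp = NULL,
                   solid_total = FALSE) {
  geom <- traj$geom; grid <- traj$grid; layout <- traj$layout
  n_f <- geom$n_fibre; n_tot <- layout$n_tot
  w <- grid$r * grid$dr
  hyd <- n_f:n_tot                       # interface node included, as printed
  fib <- seq_len(n_f)
  denom <- geom$eps_N0 * geom$rho_s * sum(w[fib])
  t_min <- traj$times / 60
  res <- list()
  for (i in dp) {
    stopifnot(i >= 1, i <= geom$m)
    pos <- layout$iA[i, hyd]
    val <- vapply(seq_along(t_min), function(s)
      sum(pmax(traj$Y[s, pos], 0) * w[hyd]), numeric(1))
    res[[length(res) + 1]] <- data.frame(
      time_min = t_min, species = paste0("X", i),
      yield_pct = 100 * val / denom, region = "hydrolysate")
  }
  if (furfural) {
    pos <- layout$iF[hyd]
    val <- vapply(seq_along(t_min), function(s)
      sum(pmax(traj$Y[s, pos], 0) * w[hyd]), numeric(1))
    res[[length(res) + 1]] <- data.frame(
      time_min = t_min, species = "furfural",
      yield_pct = 100 * val / denom, region = "hydrolysate")
  }
  for (i in solid_dp) {
    stopifnot(i > geom$m, i <= geom$N)
    pos <- layout$iS[i - geom$m, fib]
    val <- vapply(seq_along(t_min), function(s)
      sum(pmax(traj$Y[s, pos], 0) * w[fib]), numeric(1))
    res[[length(res) + 1]] <- data.frame(
      time_min = t_min, species = paste0("S", i),
      yield_pct = 100 * val / denom, region = "fibre")
  }
  if (solid_total) {
    val <- vapply(seq_along(t_min), function(s) {
      S <- matrix(pmax(traj$Y[s, layout$iS], 0), layout$n_sol, n_f)
      sum((w[fib] * colSums(S)))
    }, numeric(1))
    res[[length(res) + 1]] <- data.frame(
      time_min = t_min, species = "solid_total",
      yield_pct = 100 * val / denom, region = "fibre")
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("yield_series", "data.frame")
  out
}

#' Write/read yield series as tidy CSV
#'
#' Columns `time_min`, `species`, `yield_pct`, `region`.
#'
#' @param series A `yield_series` data.frame.
#' @param path File path.
#' @return `write_yields` returns `path` invisibly; `read_yields` the
#'   data.frame.
#' @export
write_yields <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_yields
#' @export
read_yields <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("yield_series", "data.frame")
  out
}
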