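# Pointwise population-balance reaction terms and finite-volume diffusion
# fluxes. These operate on a state_field and are the reference definition of
# the right-hand side; the integrator uses an equivalent packed closure
# (see simulate.R) that is tested against the composition of the two.

# strictly upper triangular matrix of ones: row i picks parents j > i
suffix_sum_matrix <- function(n) {
  U <- matrix(0, n, n)
  U[upper.tri(U)] <- 1
  U
}

# bulk (Stokes-Einstein) diffusivities for [furfural, chains 1..m]
bulk_diffusivities <- function(geom, T_K, D_inf = NULL, D_F_inf = NULL,
                               viscosity = water_viscosity) {
  if (is.null(D_F_inf)) D_F_inf <- geom$D_F_inf
  chain_D <- if (is.null(D_inf)) {
    BOLTZMANN * T_K / (6 * pi * viscosity(T_K) * 0.676 * geom$l *
                         sqrt(seq_len(geom$m)))
  } else {
    rep(D_inf, geom$m)
  }
  c(D_F_inf, chain_D)
}

#' Population-balance reaction rates of a state
#'
#' Evaluates the scission, formation and degradation terms at every node:
#' solid chains scise at `k_a psi phi_i`, aqueous chains at `k_b psi phi_i`,
#' xylose degrades to furfural at `k_d psi phi_1`, and every species `i`
#' gains `2 k psi sum_j Omega_{i, j-i} phi_j` from longer parents. The
#' effective acid `psi = eps_v C_H` is evaluated per node; solid terms exist
#' only on fibre nodes. Negative concentrations (integrator overshoot) are
#' clipped to zero before evaluation.
#'
#' @param state A [state_field()].
#' @param params A [kinetic_params()].
#' @param cond A [conditions()] object (supplies `C_H`).
#' @return A list with components `phi_F`, `phi_aq`, `phi_solid`: rates in
#'   kg m^-3 s^-1 with the same shapes as the state.
#' @export
reaction_terms <- function(state, params, cond) {
  geom <- state$geom
  m <- geom$m; N <- geom$N; n_sol <- N - m
  n_f <- geom$n_fibre; n_tot <- n_f + geom$n_hydro
  psi <- effective_acid(pmin(state$eps_v, 1), cond$C_H)

  A <- pmax(state$phi_aq, 0)
  S <- pmax(state$phi_solid, 0)

  w_aq <- c(0, 1 / ((2:m) * ((2:m) - 1)))      # phi_j -> s_j, monomer no parent
  w_sol <- 1 / (((m + 1):N) * (((m + 1):N) - 1))
  sA <- A * w_aq
  sS <- S * w_sol
  SA <- suffix_sum_matrix(m) %*% sA            # sum_{j = i+1}^{m} s_j
  SS <- suffix_sum_matrix(n_sol) %*% sS        # sum_{j = i+1}^{N} s_j (solid)
  B <- colSums(sS)                             # sum_{j = m+1}^{N} s_j
  Bmat <- matrix(0, m, n_tot)
  Bmat[, seq_len(n_f)] <- matrix(B, m, n_f, byrow = TRUE)

  gain_aq <- 2 * (seq_len(m)) * (params$k_b * SA + params$k_a * Bmat)
  loss_aq <- c(params$k_d, rep(params$k_b, m - 1)) * A
  r_aq <- (gain_aq - loss_aq) * rep(psi, each = m)

  i_sol <- (m + 1):N
  r_sol <- (2 * params$k_a * i_sol * SS - params$k_a * S) *
    rep(psi[seq_len(n_f)], each = n_sol)

  r_F <- params$k_d * psi * A[1, ]
  list(phi_F = r_F, phi_aq = r_aq, phi_solid = r_sol)
}

#' Finite-volume diffusion rates of a state
#'
#' Conservative vertex-centred fluxes in cylindrical coordinates for the
#' mobile species (furfural and chains `1..m`); solid chains do not
#' diffuse. Face diffusivities are harmonic means of the adjacent node
#' values (`eps_v^3 D_inf` in the fibre, `D_inf` in the hydrolysate), which
#' keeps the flux continuous across the porosity jump at the interface.
#' Zero flux is imposed at `r = 0` and `r = R_o`.
#'
#' @param state A [state_field()].
#' @param cond A [conditions()] object (supplies the temperature).
#' @param grid A [build_grid()] result (defaults to the state's own).
#' @param D_inf Optional constant bulk chain diffusivity overriding the
#'   Stokes-Einstein law (used when diffusivities are fitted).
#' @param D_F_inf Optional furfural bulk diffusivity override.
#' @param viscosity Viscosity function of temperature.
#' @return A list with components `phi_F`, `phi_aq`, `phi_solid` (the last
#'   identically zero), rates in kg m^-3 s^-1.
#' @export
diffusion_terms <- function(state, cond, grid = state$grid, D_inf = NULL,
                            D_F_inf = NULL, viscosity = water_viscosity) {
  geom <- state$geom
  m <- geom$m
  n <- length(grid$r)
  Dinf <- bulk_diffusivities(geom, cond$T_K, D_inf, D_F_inf, viscosity)
  eps3 <- pmax(state$eps_v, 0)^3                 # 1 in the hydrolysate
  d <- outer(Dinf, eps3)                         # (m+1) x n node diffusivity
  dL <- d[, -n, drop = FALSE]; dR <- d[, -1, drop = FALSE]
  Dface <- 2 * dL * dR / (dL + dR)
  Dface[dL + dR == 0] <- 0
  P <- rbind(state$phi_F, state$phi_aq)
  grad <- (P[, -1, drop = FALSE] - P[, -n, drop = FALSE]) /
    rep(grid$dr_face, each = m + 1)
  flux <- rep(grid$r_face, each = m + 1) * Dface * grad
  net <- (cbind(flux, 0) - cbind(0, flux)) / rep(grid$vol, each = m + 1)
  list(phi_F = net[1, ],
       phi_aq = net[-1, , drop = FALSE],
       phi_solid = matrix(0, geom$N - m, geom$n_fibre))
}
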