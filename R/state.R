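# State container and node-major packing used by the stiff integrator.
#
# Packed layout (node-major, required for the banded Jacobian):
#   fibre node k = 1..n_f      -> [furfural, X1..Xm, solid m+1..N]  (N+1 slots)
#   hydrolysate node k > n_f   -> [furfural, X1..Xm]                (m+1 slots)
# Diffusion then couples equal slots 101 (= N+1) positions apart in the fibre
# and m+1 apart in the hydrolysate, and all intra-node coupling is local, so
# the Jacobian is banded with half-bandwidth 2N+1 (the extra N accounts for
# the porosity dependence of face diffusivities on neighbouring-node solid
# chains).

make_layout <- function(geom) {
  n_f <- geom$n_fibre; n_tot <- n_f + geom$n_hydro
  N <- geom$N; m <- geom$m; n_sol <- N - m
  base <- integer(n_tot)
  base[seq_len(n_f)] <- (seq_len(n_f) - 1L) * (N + 1L)
  base[(n_f + 1L):n_tot] <- n_f * (N + 1L) +
    (seq_len(n_tot - n_f) - 1L) * (m + 1L)
  iF <- base + 1L
  iA <- outer(1L + seq_len(m), base, `+`)            # m x n_tot
  iS <- outer(1L + m + seq_len(n_sol), base[seq_len(n_f)], `+`)  # n_sol x n_f
  list(n_f = n_f, n_tot = n_tot, N = N, m = m, n_sol = n_sol,
       iF = iF, iA = iA, iS = iS,
       n_states = n_f * (N + 1L) + (n_tot - n_f) * (m + 1L),
       bandwidth = 2L * N + 1L)
}

pack_state <- function(state, layout) {
  y <- numeric(layout$n_states)
  y[layout$iF] <- state$phi_F
  y[layout$iA] <- state$phi_aq
  y[layout$iS] <- state$phi_solid
  y
}

unpack_state <- function(y, layout) {
  list(phi_F = y[layout$iF],
       phi_aq = matrix(y[layout$iA], layout$m, layout$n_tot),
       phi_solid = matrix(y[layout$iS], layout$n_sol, layout$n_f))
}

#' Construct a state field
#'
#' Volume-averaged mass concentrations of every tracked species on the
#' radial grid: furfural and aqueous chains `1..m` on all nodes, solid
#' chains `m+1..N` on fibre nodes only. The fibre porosity is derived from
#' the solid concentrations via the conservation-of-volume closure and
#' stored alongside.
#'
#' @param geom A [material_geometry()].
#' @param phi_F Furfural concentration per node (kg m^-3).
#' @param phi_aq Matrix (`m` x nodes) of aqueous chain concentrations.
#' @param phi_solid Matrix (`N - m` x fibre nodes) of solid chain
#'   concentrations.
#' @param alpha Hard-to-hydrolyse fraction (enters the porosity closure).
#' @param grid Optional pre-built [build_grid()] result.
#' @return An object of class `state_field`.
#' @export
state_field <- function(geom, phi_F, phi_aq, phi_solid, alpha = 0,
                        grid = build_grid(geom)) {
  n_tot <- geom$n_fibre + geom$n_hydro
  stopifnot(
    length(phi_F) == n_tot,
    is.matrix(phi_aq), nrow(phi_aq) == geom$m, ncol(phi_aq) == n_tot,
    is.matrix(phi_solid), nrow(phi_solid) == geom$N - geom$m,
    ncol(phi_solid) == geom$n_fibre,
    "concentrations must be non-negative" =
      all(phi_F >= 0) && all(phi_aq >= 0) && all(phi_solid >= 0)
  )
  eps_v <- rep(1, n_tot)
  eps_v[seq_len(geom$n_fibre)] <- porosity(phi_solid, geom, alpha)
  structure(list(geom = geom, grid = grid, phi_F = phi_F, phi_aq = phi_aq,
                 phi_solid = phi_solid, eps_v = eps_v, alpha = alpha),
            class = "state_field")
}

#' @export
print.state_field <- function(x, ...) {
  cat(sprintf("<state_field> %d nodes, chains 1..%d aqueous + %d..%d solid\n",
              length(x$phi_F), x$geom$m, x$geom$m + 1, x$geom$N))
  cat(sprintf("  fibre porosity range: [%.4f, %.4f]\n",
              min(x$eps_v[seq_len(x$geom$n_fibre)]),
              max(x$eps_v[seq_len(x$geom$n_fibre)])))
  invisible(x)
}

#' Initial monodisperse state
#'
#' All reactive hemicellulose starts as solid chains of the maximum length
#' `N`, uniformly distributed over the fibre at concentration
#' `(1 - alpha) * eps_N0 * rho_s`; every other species is zero everywhere,
#' and the hydrolysate is pure acid solution.
#'
#' @param geom A [material_geometry()].
#' @param cond A [conditions()] object (unused numerically here; kept so the
#'   initial state documents the run it belongs to).
#' @param params A [kinetic_params()] object; only `alpha` is used.
#' @return A [state_field()].
#' @export
initial_state <- function(geom, cond, params) {
  n_tot <- geom$n_fibre + geom$n_hydro
  phi_solid <- matrix(0, geom$N - geom$m, geom$n_fibre)
  phi_solid[geom$N - geom$m, ] <- (1 - params$alpha) * geom$eps_N0 * geom$rho_s
  state_field(geom,
              phi_F = numeric(n_tot),
              phi_aq = matrix(0, geom$m, n_tot),
              phi_solid = phi_solid,
              alpha = params$alpha)
}

#' Total cylindrical mass of tracked species in a state
#'
#' Cell-measure-weighted sum (per unit fibre length, per radian) of
#' furfural, aqueous and solid chain concentrations, optionally including
#' the static unreactive hemicellulose mass. Constant along any trajectory
#' of the closed system.
#'
#' @param state A [state_field()].
#' @param include_unreactive Add `alpha * eps_N0 * rho_s` over the fibre.
#' @return Mass (kg m^-1 rad^-1).
#' @export
total_mass <- function(state, include_unreactive = FALSE) {
  v <- state$grid$vol
  n_f <- state$geom$n_fibre
  m <- sum(state$phi_F * v) + sum(state$phi_aq %*% v) +
    sum(state$phi_solid %*% v[seq_len(n_f)])
  if (include_unreactive)
    m <- m + state$alpha * state$geom$eps_N0 * state$geom$rho_s *
      sum(v[seq_len(n_f)])
  m
}
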