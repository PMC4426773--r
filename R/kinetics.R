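#' Random-scission breakage kernel
#'
#' Weight `Omega_{i, j-i} = i / (j (j - 1))` giving the contribution of a
#' parent chain of length `j` to fragments of length `i` under random
#' scission of mass-based concentrations. With the gain factor 2 and unit
#' loss used in the population balance, the kernel closes mass exactly:
#' `sum_{i=1}^{j-1} 2 * Omega_{i, j-i} = 1` for every `j >= 2`.
#'
#' @param i Fragment length(s), `1 <= i < j`.
#' @param j Parent chain length(s), `j >= 2`.
#' @return Kernel weight(s), dimensionless.
#' @examples
#' breakage_kernel(1, 2)            # 0.5: a dimer has a single bond
#' sum(2 * breakage_kernel(1:9, 10)) # exactly 1
#' @export
breakage_kernel <- function(i, j) {
  if (any(i < 1) || any(i >= j))
    stop("breakage kernel requires 1 <= i < j", call. = FALSE)
  i / (j * (j - 1))
}

#' Evaluate an Arrhenius law
#'
#' @param fit An [arrhenius_fit()] object.
#' @param T_K Temperature(s) in Kelvin.
#' @return Rate constant(s) `k0 * exp(-Ea / (R T))` in m^3 mol^-1 s^-1.
#' @export
arrhenius_rate <- function(fit, T_K) {
  if (any(T_K <= 0)) stop("temperature must be positive (K)", call. = FALSE)
  fit$k0 * exp(-fit$Ea / (GAS_CONSTANT * T_K))
}

#' Evaluate the hard-to-hydrolyse fraction law
#'
#' `alpha(T) = A exp(-b T)`. The exponential form guarantees a vanishing
#' unreactive fraction at high temperature but grows without bound as the
#' temperature drops, so evaluation is refused where it would reach 1
#' (below the law's validity window).
#'
#' @param law An [alpha_law()] object.
#' @param T_K Temperature(s) in Kelvin.
#' @return alpha in `[0, 1)`.
#' @export
alpha_of_T <- function(law, T_K) {
  if (any(T_K <= 0)) stop("temperature must be positive (K)", call. = FALSE)
  a <- law$A * exp(-law$b * T_K)
  if (any(a >= 1))
    stop("alpha(T) >= 1: temperature below the validity window of the ",
         "exponential law", call. = FALSE)
  a
}

#' Effective acid concentration in a porous node
#'
#' The pores are assumed instantly filled with acid at the bulk
#' concentration, so the volume-averaged catalytic concentration is
#' `psi = eps_v * C_H`. Hydrolysate nodes have `eps_v = 1`.
#'
#' @param eps_v Porosity (void volume fraction), in `[0, 1]`.
#' @param C_H Bulk acid concentration (mol m^-3).
#' @return Effective acid concentration (mol m^-3).
#' @export
effective_acid <- function(eps_v, C_H) {
  if (any(eps_v < 0 | eps_v > 1))
    stop("porosity must lie in [0, 1]", call. = FALSE)
  eps_v * C_H
}

#' Dynamic viscosity of water
#'
#' Vogel correlation `eta = A exp(B / (T - C))` with the usual liquid-water
#' constants (A = 2.939e-5 Pa s, B = 507.88 K, C = 149.3 K). The 0.5 wt%
#' acid solution is treated as water.
#'
#' @param T_K Temperature(s) in Kelvin.
#' @return Viscosity in Pa s (kg m^-1 s^-1).
#' @export
water_viscosity <- function(T_K) {
  2.939e-5 * exp(507.88 / (T_K - 149.3))
}

#' Effective diffusivity of a mobile species
#'
#' Bulk diffusivities follow a modified Stokes-Einstein law,
#' `D_inf(i) = k_B T / (6 pi eta R_h(i))` with hydrodynamic radius
#' `R_h(i) = 0.676 l sqrt(i)`; furfural uses the fixed bulk value
#' `D_F_inf`. Inside the fibre the tortuosity factor `eps_v^3` applies,
#' `D_eff = eps_v^3 D_inf`; in the hydrolysate `eps_v = 1` and the bulk
#' value is recovered.
#'
#' @param i Chain length (positive integer) or the string `"furfural"`.
#' @param T_K Temperature in Kelvin.
#' @param eps_v Porosity, in `[0, 1]` (1 in the hydrolysate).
#' @param geom A [material_geometry()] (supplies `l` and `D_F_inf`).
#' @param viscosity Function of temperature returning Pa s.
#' @return Effective diffusivity (m^2 s^-1).
#' @examples
#' diffusivity(1, 383.15, eps_v = 1) / diffusivity(4, 383.15, eps_v = 1) # 2
#' @export
diffusivity <- function(i, T_K, eps_v = 1, geom = material_geometry(),
                        viscosity = water_viscosity) {
  if (any(eps_v < 0 | eps_v > 1))
    stop("porosity must lie in [0, 1]", call. = FALSE)
  if (T_K <= 0) stop("temperature must be positive (K)", call. = FALSE)
  if (identical(i, "furfural")) {
    D_inf <- geom$D_F_inf
  } else {
    if (any(i < 1)) stop("chain length must be >= 1", call. = FALSE)
    R_h <- 0.676 * geom$l * sqrt(i)
    D_inf <- BOLTZMANN * T_K / (6 * pi * viscosity(T_K) * R_h)
  }
  eps_v^3 * D_inf
}

#' Fibre porosity from the solid chain concentrations
#'
#' Conservation-of-volume closure: the void fraction is what the fixed
#' lignocellulose, the remaining reactive solid xylan (`eps_i = phi_i /
#' rho_s`) and the unreactive hemicellulose (`eps_alpha = alpha * eps_N0`)
#' leave unoccupied. Porosity grows monotonically as solid xylan dissolves,
#' from `1 - (F_hat + eps_N0)` initially to `1 - (F_hat + alpha * eps_N0)`.
#'
#' @param solid_phi Numeric vector or matrix of solid-chain concentrations
#'   (kg m^-3); when a matrix, rows are chain lengths `m+1..N` and columns
#'   are fibre nodes.
#' @param geom A [material_geometry()].
#' @param alpha Hard-to-hydrolyse fraction.
#' @return Porosity per node, in `(0, 1)`.
#' @export
porosity <- function(solid_phi, geom, alpha = 0) {
  if (any(solid_phi < 0))
    stop("solid concentrations must be non-negative", call. = FALSE)
  tot <- if (is.matrix(solid_phi)) colSums(solid_phi) else sum(solid_phi)
  eps_v <- 1 - (geom$F_hat + tot / geom$rho_s + alpha * geom$eps_N0)
  if (any(eps_v <= 0))
    stop("computed porosity <= 0: solid volume exceeds available space",
         call. = FALSE)
  eps_v
}
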