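#' Material and geometry description of a bagasse fibre
#'
#' Bundles the composition volume fractions, chain-length limits and the
#' cylindrical two-region (fibre + hydrolysate) geometry of the model domain.
#' Defaults are the standard simulation constants for milled sugarcane
#' bagasse in 0.5 wt% sulfuric acid.
#'
#' @param F_hat Fixed (non-reacting) lignocellulose volume fraction of the
#'   fibre: cellulose + lignin + ash, assumed constant during hydrolysis.
#' @param eps_N0 Initial total hemicellulose (xylan) volume fraction of the
#'   fibre. Together with `F_hat` this sets the initial porosity
#'   `1 - (F_hat + eps_N0)`.
#' @param rho_s Density of solid xylan (kg m^-3). Only the porosity feedback
#'   depends on it; all yields are invariant to its value.
#' @param N Maximum chain length (degree of polymerisation) tracked.
#' @param m Solubility cutoff: chains of length `<= m` are aqueous (mobile),
#'   longer chains are solid xylan confined to the fibre.
#' @param l Monomer segment length (m), used in the hydrodynamic radius
#'   `R_h(i) = 0.676 * l * sqrt(i)`.
#' @param R_i Fibre radius (m).
#' @param hydrolysate_factor Ratio `(R_o - R_i) / R_i` of the hydrolysate
#'   annulus thickness to the fibre radius.
#' @param n_fibre,n_hydro Number of uniformly spaced finite-volume nodes in
#'   the fibre (including the centre and interface nodes) and in the
#'   hydrolysate annulus.
#' @param D_F_inf Bulk diffusivity of furfural in water (m^2 s^-1).
#'
#' @return An object of class `material_geometry`.
#' @seealso [build_grid()], [initial_state()], [porosity()]
#' @examples
#' geom <- material_geometry()
#' geom$R_i * (1 + geom$hydrolysate_factor)  # outer radius R_o
#' @export
material_geometry <- function(F_hat = 0.581, eps_N0 = 0.165, rho_s = 1500,
                              N = 100L, m = 15L, l = 0.65e-9, R_i = 3.75e-4,
                              hydrolysate_factor = 2.32,
                              n_fibre = 100L, n_hydro = 250L,
                              D_F_inf = 1.12e-9) {
  N <- as.integer(N); m <- as.integer(m)
  n_fibre <- as.integer(n_fibre); n_hydro <- as.integer(n_hydro)
  stopifnot(
    "F_hat + eps_N0 must lie in (0, 1)" =
      F_hat > 0 && eps_N0 > 0 && F_hat + eps_N0 < 1,
    "need 1 < m < N" = m > 1L && m < N,
    "R_i must be positive" = R_i > 0,
    "hydrolysate_factor must be positive" = hydrolysate_factor > 0,
    "rho_s must be positive" = rho_s > 0,
    "segment length l must be positive" = l > 0,
    "D_F_inf must be positive" = D_F_inf > 0,
    "node counts must be >= 3" = n_fibre >= 3L && n_hydro >= 3L
  )
  structure(list(F_hat = F_hat, eps_N0 = eps_N0, rho_s = rho_s, N = N, m = m,
                 l = l, R_i = R_i, hydrolysate_factor = hydrolysate_factor,
                 n_fibre = n_fibre, n_hydro = n_hydro, D_F_inf = D_F_inf),
            class = "material_geometry")
}

#' @export
print.material_geometry <- function(x, ...) {
  cat("<material_geometry>\n")
  cat(sprintf("  fibre: R_i = %.3g m, %d nodes; hydrolysate: (R_o-R_i)/R_i = %.3g, %d nodes\n",
              x$R_i, x$n_fibre, x$hydrolysate_factor, x$n_hydro))
  cat(sprintf("  chains: N = %d, soluble up to m = %d; l = %.3g m\n",
              x$N, x$m, x$l))
  cat(sprintf("  volume fractions: F_hat = %.3f, eps_N0 = %.3f (initial porosity %.3f)\n",
              x$F_hat, x$eps_N0, 1 - x$F_hat - x$eps_N0))
  cat(sprintf("  rho_s = %g kg/m^3, D_F_inf = %.3g m^2/s\n", x$rho_s, x$D_F_inf))
  invisible(x)
}

#' Operating conditions for a hydrolysis simulation
#'
#' @param T_K Temperature in Kelvin (isothermal). Use `celsius_to_kelvin()`
#'   for degree-Celsius inputs.
#' @param C_H Bulk hydronium concentration (mol m^-3); 51 mol m^-3
#'   corresponds to 0.5 wt% sulfuric acid with single deprotonation.
#' @param t_end Simulation horizon in seconds.
#' @param output_times Strictly increasing times (s) at which the state is
#'   reported; defaults to 121 equispaced points on `[0, t_end]`.
#'
#' @return An object of class `hydrolysis_conditions`.
#' @examples
#' conditions(T_K = celsius_to_kelvin(110), t_end = 360 * 60)
#' @export
conditions <- function(T_K, C_H = 51, t_end, output_times = NULL) {
  if (is.null(output_times)) output_times <- seq(0, t_end, length.out = 121)
  stopifnot(
    "temperature must be positive (Kelvin)" = T_K > 0,
    "C_H must be non-negative" = C_H >= 0,
    "t_end must be positive" = t_end > 0,
    "output_times must be strictly increasing" =
      all(diff(output_times) > 0),
    "output_times must lie within [0, t_end]" =
      min(output_times) >= 0 && max(output_times) <= t_end
  )
  structure(list(T_K = T_K, C_H = C_H, t_end = t_end,
                 output_times = as.numeric(output_times)),
            class = "hydrolysis_conditions")
}

#' @export
print.hydrolysis_conditions <- function(x, ...) {
  cat(sprintf("<hydrolysis_conditions> T = %.2f K (%.1f degC), C_H = %g mol/m^3, t_end = %g min\n",
              x$T_K, x$T_K - 273.15, x$C_H, x$t_end / 60))
  invisible(x)
}

#' Kinetic parameter set at one temperature
#'
#' @param k_a Scission rate constant for solid xylan chains (m^3 mol^-1 s^-1).
#' @param k_b Scission rate constant for aqueous chains (m^3 mol^-1 s^-1).
#' @param k_d Xylose-to-furfural degradation rate constant (m^3 mol^-1 s^-1).
#' @param alpha Hard-to-hydrolyse fraction: the portion of hemicellulose
#'   treated as unreactive on the hydrolysis timescale, in `[0, 1]`
#'   (`alpha = 1` is the degenerate fully unreactive limit).
#'
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(k_a = 2.0630e-4, k_b = 1.5434e-5, k_d = 7.9618e-9,
#'                alpha = 0.32016)
#' @export
kinetic_params <- function(k_a, k_b, k_d, alpha = 0) {
  stopifnot(
    "rate constants must be non-negative" = k_a >= 0 && k_b >= 0 && k_d >= 0,
    "alpha must lie in [0, 1]" = alpha >= 0 && alpha <= 1
  )
  structure(list(k_a = k_a, k_b = k_b, k_d = k_d, alpha = alpha),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> k_a = %.4e, k_b = %.4e, k_d = %.4e m^3/mol/s; alpha = %.5f\n",
              x$k_a, x$k_b, x$k_d, x$alpha))
  invisible(x)
}

#' Arrhenius law for a rate constant
#'
#' `k(T) = k0 * exp(-Ea / (R T))` with `R = 8.314` J K^-1 mol^-1.
#'
#' @param k0 Pre-exponential factor (m^3 mol^-1 s^-1).
#' @param Ea Activation energy (J mol^-1).
#' @return An object of class `arrhenius_fit`.
#' @export
arrhenius_fit <- function(k0, Ea) {
  stopifnot("k0 must be positive" = k0 > 0,
            "Ea must be non-negative" = Ea >= 0)
  structure(list(k0 = k0, Ea = Ea), class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> k0 = %.4e m^3/mol/s, Ea = %.4e J/mol\n",
              x$k0, x$Ea))
  invisible(x)
}

#' Exponential temperature law for the hard-to-hydrolyse fraction
#'
#' `alpha(T) = A * exp(-b T)`, valid over the calibrated temperature window
#' (roughly 383-443 K); it diverges above 1 at lower temperatures.
#'
#' @param A Dimensionless prefactor.
#' @param b Decay constant (K^-1).
#' @return An object of class `alpha_law`.
#' @export
alpha_law <- function(A = 4.1820e9, b = 6.0514e-2) {
  stopifnot("A must be positive" = A > 0,
            "b must be positive" = b > 0)
  structure(list(A = A, b = b), class = "alpha_law")
}

#' @export
print.alpha_law <- function(x, ...) {
  cat(sprintf("<alpha_law> alpha(T) = %.4e * exp(-%.4e * T)\n", x$A, x$b))
  invisible(x)
}

#' Convert degrees Celsius to Kelvin
#'
#' @param T_C Temperature in degrees Celsius.
#' @return Temperature in Kelvin.
#' @export
celsius_to_kelvin <- function(T_C) T_C + 273.15

#' Universal gas constant (J K^-1 mol^-1)
#' @export
GAS_CONSTANT <- 8.314

#' Boltzmann constant (m^2 kg s^-2 K^-1)
#' @export
BOLTZMANN <- 1.38e-23
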