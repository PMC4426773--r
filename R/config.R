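# YAML model configuration mirroring the standard simulation constants.
# Only the xylan fraction of the composition block is consumed
# computationally; the remaining fractions are stored metadata.

#' Default model configuration
#'
#' Nested list mirroring the standard parameter set: material volume
#' fractions and chain-length limits, grid sizes, operating conditions,
#' solver tolerances, physical constants and the bagasse composition.
#'
#' @return A list of class `hydrolysis_config`.
#' @export
default_config <- function() {
  structure(list(
    material = list(F_hat = 0.581, eps_N0 = 0.165, rho_s = 1500,
                    N = 100L, m = 15L, l = 0.65e-9, R_i = 3.75e-4,
                    hydrolysate_factor = 2.32, D_F_inf = 1.12e-9),
    grid = list(n_fibre = 100L, n_hydro = 250L),
    conditions = list(T_C = 110, C_H = 51, t_end_min = 360),
    solver = list(rtol = 1e-7, atol = 1e-10),
    constants = list(k_B = 1.38e-23, R = 8.314),
    composition = list(glucan = 0.438, xylan = 0.202, arabinan = 0.033,
                       lignin = 0.275, acetyl = 0.025, ash = 0.021),
    sample = list(dry_mass_g = 4.68)),
    class = "hydrolysis_config")
}

# recursively overlay user values onto defaults
merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read or write a model configuration YAML
#'
#' Values absent from the file keep their defaults.
#'
#' @param path YAML file path.
#' @return `read_config`: a `hydrolysis_config` list; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), user)
  class(cfg) <- "hydrolysis_config"
  cfg
}

#' @rdname read_config
#' @param cfg A `hydrolysis_config` list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build model objects from a configuration
#'
#' @param cfg A `hydrolysis_config` list.
#' @return `geometry_from_config`: a [material_geometry()];
#'   `conditions_from_config`: a [conditions()];
#'   `solver_from_config`: a [solver_control()];
#'   `sample_from_config`: a [bagasse_sample()].
#' @export
geometry_from_config <- function(cfg) {
  m <- cfg$material
  material_geometry(F_hat = m$F_hat, eps_N0 = m$eps_N0, rho_s = m$rho_s,
                    N = m$N, m = m$m, l = m$l, R_i = m$R_i,
                    hydrolysate_factor = m$hydrolysate_factor,
                    n_fibre = cfg$grid$n_fibre, n_hydro = cfg$grid$n_hydro,
                    D_F_inf = m$D_F_inf)
}

#' @rdname geometry_from_config
#' @param T_C,t_end_min,output_times_min Optional overrides of the
#'   configured temperature (degC), horizon and output times (minutes).
#' @export
conditions_from_config <- function(cfg, T_C = NULL, t_end_min = NULL,
                                   output_times_min = NULL) {
  cc <- cfg$conditions
  if (is.null(T_C)) T_C <- cc$T_C
  if (is.null(t_end_min)) t_end_min <- cc$t_end_min
  out <- if (is.null(output_times_min)) NULL else output_times_min * 60
  conditions(T_K = celsius_to_kelvin(T_C), C_H = cc$C_H,
             t_end = t_end_min * 60, output_times = out)
}

#' @rdname geometry_from_config
#' @export
solver_from_config <- function(cfg) {
  solver_control(rtol = cfg$solver$rtol, atol = cfg$solver$atol)
}

#' @rdname geometry_from_config
#' @export
sample_from_config <- function(cfg) {
  bagasse_sample(dry_mass_g = cfg$sample$dry_mass_g,
                 xylan_fraction = cfg$composition$xylan)
}
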