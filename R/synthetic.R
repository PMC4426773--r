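# Pseudo-experimental data with the statistical structure the calibration
# assumes: forward-simulated yields at sparse time points with seeded
# multiplicative + additive Gaussian noise, plus a sidecar file recording
# the generating truth for parameter-recovery studies.

#' Measurement noise model for synthetic experiments
#'
#' Observed yield = `y * (1 + e_rel) + e_abs` with independent Gaussian
#' `e_rel ~ N(0, rel_sd^2)` and `e_abs ~ N(0, abs_sd^2)`, clipped at zero.
#' The defaults (5% relative, 0.2 yield-% absolute) emulate the scatter of
#' typical HPLC oligomer yield measurements; they are a synthetic choice,
#' not an experimentally calibrated error model.
#'
#' @param rel_sd Relative (multiplicative) standard deviation.
#' @param abs_sd Absolute standard deviation (yield %).
#' @param seed Integer seed making the generated data reproducible.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(rel_sd = 0.05, abs_sd = 0.2, seed = 1L) {
  stopifnot("standard deviations must be >= 0" = rel_sd >= 0 && abs_sd >= 0)
  structure(list(rel_sd = rel_sd, abs_sd = abs_sd, seed = as.integer(seed)),
            class = "noise_model")
}

#' Generate a synthetic experiment
#'
#' Forward-simulates the model at known parameters, evaluates the yield
#' curves at sparse sampling times (mirroring the experimental horizons,
#' e.g. 0-360 min at 110 degC), applies the seeded noise model and clips
#' at zero. Optionally writes the observations in the experiment CSV
#' dialect plus a sidecar JSON recording the generating parameters, so
#' recovery studies can compare fitted against true values.
#'
#' @param params Generating [kinetic_params()].
#' @param geom,cond Model configuration for the forward simulation.
#' @param sample_times_min Sampling times (minutes).
#' @param noise A [noise_model()].
#' @param species Species labels to observe.
#' @param path Optional CSV output path.
#' @param sidecar_path Optional JSON truth output path.
#' @param control A [solver_control()].
#' @return Data.frame `species`, `time_min`, `yield_pct` with the noiseless
#'   model values attached as attribute `truth`.
#' @export
generate_experiment <- function(params, geom, cond,
                                sample_times_min =
                                  c(15, 30, 60, 120, 180, 240, 300, 360),
                                noise = noise_model(),
                                species = c("furfural", paste0("X", 1:6)),
                                path = NULL, sidecar_path = NULL,
                                control = solver_control()) {
  stopifnot(max(sample_times_min) * 60 <= cond$t_end)
  want <- parse_species(species, geom$m)
  traj <- simulate_hydrolysis(geom, cond, params, control)
  series <- yields(traj, dp = want$dp, furfural = want$furfural)
  mod <- model_at_times(series, sample_times_min)
  # canonical row order (locale-independent), so the seeded noise stream
  # maps to observations reproducibly
  canon <- c("furfural", paste0("X", seq_len(geom$m)))
  mod <- mod[order(match(mod$species, canon), mod$time_min), ]
  n <- nrow(mod)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(noise$seed)
  noisy <- mod$yield_pct * (1 + stats::rnorm(n, 0, noise$rel_sd)) +
    stats::rnorm(n, 0, noise$abs_sd)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())

  out <- data.frame(species = mod$species, time_min = mod$time_min,
                    yield_pct = pmax(noisy, 0))
  rownames(out) <- NULL
  attr(out, "truth") <- mod
  if (!is.null(path)) write_experiment(out, path)
  if (!is.null(sidecar_path)) {
    jsonlite::write_json(
      list(params = unclass(params),
           T_K = cond$T_K, C_H = cond$C_H,
           noise = unclass(noise),
           sample_times_min = sample_times_min,
           species = species),
      sidecar_path, auto_unbox = TRUE, digits = NA)
  }
  out
}
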