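# Calibration: bounded Levenberg-Marquardt fitting of the kinetic
# parameters against experimental yield series, plus the closed-form
# temperature regressions used to predict unseen temperatures.

FITTABLE <- c("k_a", "k_b", "k_d", "alpha", "D_inf", "D_F_inf")

#' Interpolate model yield curves at requested times
#'
#' Cubic-spline interpolation of each species' yield curve at the
#' experimental time points.
#'
#' @param series A `yield_series` data.frame (from [yields()]).
#' @param times_min Times (minutes) at which values are needed; must lie
#'   within the simulated horizon (no extrapolation).
#' @return A data.frame `time_min`, `species`, `yield_pct`.
#' @export
model_at_times <- function(series, times_min) {
  out <- lapply(split(series, series$species), function(d) {
    if (min(times_min) < min(d$time_min) - 1e-9 ||
        max(times_min) > max(d$time_min) + 1e-9)
      stop("requested times outside the simulated horizon", call. = FALSE)
    f <- stats::splinefun(d$time_min, d$yield_pct, method = "fmm")
    data.frame(time_min = times_min, species = d$species[1],
               yield_pct = f(times_min))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# parse "X3" -> dp 3; validate labels
parse_species <- function(species, m) {
  lab <- unique(species)
  bad <- lab[!(lab == "furfural" | grepl("^X[0-9]+$", lab))]
  if (length(bad))
    stop("unknown species label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  dp <- as.integer(sub("^X", "", lab[lab != "furfural"]))
  if (length(dp) && max(dp) > m)
    stop("species beyond the solubility cutoff m = ", m, call. = FALSE)
  list(dp = sort(dp), furfural = "furfural" %in% lab)
}

#' Least-squares residuals of the model against observations
#'
#' Simulates the model at the given parameters, interpolates the yield
#' curves to the observation times and returns `model - observed` with
#' equal weights, one entry per observation. The sum of squared entries is
#' the objective `Phi` (in squared yield-%).
#'
#' @param par Named numeric vector of parameter values overriding
#'   `base_params`; names from `k_a`, `k_b`, `k_d`, `alpha`, `D_inf`,
#'   `D_F_inf`.
#' @param experiments Data.frame with columns `species`, `time_min`,
#'   `yield_pct` (species in `furfural`, `X1`..`X6`).
#' @param geom,cond,base_params,control Model configuration; `base_params`
#'   supplies values for parameters not present in `par`.
#' @return Numeric residual vector with attributes `Phi` and `model` (the
#'   interpolated model values).
#' @export
hydrolysis_objective <- function(par, experiments, geom, cond,
                                 base_params = kinetic_params(0, 0, 0),
                                 control = solver_control()) {
  stopifnot(all(c("species", "time_min", "yield_pct") %in%
                  names(experiments)))
  if (!is.null(names(par)) && length(par)) {
    bad <- setdiff(names(par), FITTABLE)
    if (length(bad)) stop("unknown parameter(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  p <- base_params
  for (nm in intersect(names(par), c("k_a", "k_b", "k_d", "alpha")))
    p[[nm]] <- unname(par[[nm]])
  params <- kinetic_params(p$k_a, p$k_b, p$k_d, p$alpha)
  if ("D_inf" %in% names(par)) control$D_inf <- unname(par[["D_inf"]])
  if ("D_F_inf" %in% names(par)) control$D_F_inf <- unname(par[["D_F_inf"]])

  want <- parse_species(experiments$species, geom$m)
  t_obs_s <- sort(unique(experiments$time_min)) * 60
  if (max(t_obs_s) > cond$t_end)
    stop("observations beyond the simulation horizon", call. = FALSE)
  traj <- simulate_hydrolysis(geom, cond, params, control)
  series <- yields(traj, dp = want$dp, furfural = want$furfural)
  mod <- model_at_times(series, experiments$time_min)
  key <- function(d) paste(d$species, signif(d$time_min, 10))
  model_val <- mod$yield_pct[match(key(experiments), key(mod))]
  res <- model_val - experiments$yield_pct
  attr(res, "Phi") <- sum(res^2)
  attr(res, "model") <- model_val
  res
}

#' Fitting control settings
#'
#' Mirrors the recommended control data of a Gauss-Marquardt-Levenberg
#' parameter-estimation run: at most `maxiter` iterations, stopping early
#' once the relative improvement of `Phi` over `n_phi_stop` iterations
#' falls below `phi_stop`; Jacobians by forward differences with relative
#' increment `rel_inc` and a per-parameter absolute lower increment bound.
#'
#' @param maxiter Maximum LM iterations.
#' @param phi_stop Relative `Phi` improvement threshold.
#' @param n_phi_stop Window (iterations) over which the improvement is
#'   measured.
#' @param rel_inc Relative finite-difference increment.
#' @param derinclb Named vector of absolute lower increment bounds; filled
#'   with defaults for missing parameters.
#' @param multi_start Number of additional Latin-hypercube starting points
#'   (0 = single start, as in the original calibration).
#' @param seed Seed for the multi-start sampling.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(maxiter = 30L, phi_stop = 0.005, n_phi_stop = 4L,
                        rel_inc = 0.01, derinclb = NULL, multi_start = 0L,
                        seed = 0L) {
  default_inclb <- c(k_a = 1e-8, k_b = 1e-9, k_d = 1e-12, alpha = 1e-4,
                     D_inf = 1e-12, D_F_inf = 1e-12)
  if (is.null(derinclb)) derinclb <- default_inclb
  else {
    miss <- setdiff(names(default_inclb), names(derinclb))
    derinclb <- c(derinclb, default_inclb[miss])
  }
  structure(list(maxiter = as.integer(maxiter), phi_stop = phi_stop,
                 n_phi_stop = as.integer(n_phi_stop), rel_inc = rel_inc,
                 derinclb = derinclb, multi_start = as.integer(multi_start),
                 seed = as.integer(seed)),
            class = "fit_control")
}

default_bounds <- function(free) {
  lower <- c(k_a = 0, k_b = 0, k_d = 0, alpha = 0, D_inf = 0, D_F_inf = 0)
  upper <- c(k_a = 1, k_b = 1, k_d = 1, alpha = 0.9,
             D_inf = 1e-6, D_F_inf = 1e-6)
  list(lower = lower[free], upper = upper[free])
}

# one bounded LM run with windowed Phi stopping
lm_windowed <- function(fn, jac, start, lower, upper, fctrl) {
  par <- start
  phi_trace <- sum(fn(par)^2)
  iters_done <- 0L
  termination <- "maxiter"
  while (iters_done < fctrl$maxiter) {
    chunk <- min(fctrl$n_phi_stop, fctrl$maxiter - iters_done)
    # maxiter warnings are expected: iterations are chunked so the
    # windowed Phi-improvement stop can be applied between chunks
    res <- withCallingHandlers(
      minpack.lm::nls.lm(
        par = par, lower = lower, upper = upper, fn = fn, jac = jac,
        control = minpack.lm::nls.lm.control(
          maxiter = chunk, ftol = 0, ptol = 0, gtol = 0)),
      warning = function(w) {
        if (grepl("maxiter", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    par <- stats::coef(res)
    iters_done <- iters_done + max(res$niter, 1L)
    phi_trace <- c(phi_trace, res$deviance)
    n_back <- length(phi_trace)
    phi_old <- phi_trace[n_back - 1]
    if (phi_old <= 0 ||
        (phi_old - res$deviance) / phi_old < fctrl$phi_stop) {
      termination <- "phi_improvement"
      break
    }
  }
  list(par = par, phi_trace = phi_trace, iterations = iters_done,
       termination = termination)
}

#' Fit kinetic parameters to experimental yield series
#'
#' Bounded Levenberg-Marquardt minimisation of the equally weighted sum of
#' squared yield residuals `Phi`. Supports the three standard fitting
#' regimes: rates only (`k_a`, `k_b`, `k_d`, with `alpha` fixed at 0), the
#' four-parameter fit including the hard-to-hydrolyse fraction, and the
#' rates plus bulk diffusivities (`D_inf`, `D_F_inf`) with `alpha = 0`.
#'
#' @param experiments Data.frame `species`, `time_min`, `yield_pct`.
#' @param geom,cond Model configuration used for every forward simulation.
#' @param free Character vector of parameters to vary.
#' @param start Named start values for the free parameters (defaults are
#'   mid-range guesses).
#' @param lower,upper Named bounds; defaults keep rates in `[0, 1]`
#'   m^3 mol^-1 s^-1 and `alpha` in `[0, 0.9]` (non-physical values
#'   excluded).
#' @param base_params Values of the non-free parameters.
#' @param fctrl A [fit_control()].
#' @param control A [solver_control()] for the forward model.
#' @return An object of class `fit_result`: fitted [kinetic_params()], the
#'   free-parameter vector, `Phi`, residuals, per-species residual summary
#'   and convergence diagnostics.
#' @export
fit_kinetics <- function(experiments, geom, cond,
                         free = c("k_a", "k_b", "k_d", "alpha"),
                         start = NULL, lower = NULL, upper = NULL,
                         base_params = kinetic_params(0, 0, 0),
                         fctrl = fit_control(),
                         control = solver_control()) {
  free <- match.arg(free, FITTABLE, several.ok = TRUE)
  bounds <- default_bounds(free)
  if (!is.null(lower)) bounds$lower[names(lower)] <- lower
  if (!is.null(upper)) bounds$upper[names(upper)] <- upper
  start_default <- c(k_a = 1e-4, k_b = 1e-5, k_d = 1e-8, alpha = 0.1,
                     D_inf = 1e-9, D_F_inf = 1.12e-9)[free]
  if (!is.null(start)) start_default[names(start)] <- start
  start <- pmin(pmax(start_default, bounds$lower), bounds$upper)
  stopifnot(all(is.finite(bounds$lower)), all(is.finite(bounds$upper)),
            all(start >= bounds$lower & start <= bounds$upper))

  fn <- function(p) {
    names(p) <- free
    as.numeric(hydrolysis_objective(p, experiments, geom, cond,
                                    base_params, control))
  }
  inclb <- fctrl$derinclb[free]
  jac <- function(p, ...) {
    names(p) <- free
    r0 <- fn(p)
    J <- matrix(0, length(r0), length(p))
    for (k in seq_along(p)) {
      h <- max(fctrl$rel_inc * abs(p[k]), inclb[k])
      p2 <- p; p2[k] <- p[k] + h
      J[, k] <- (fn(p2) - r0) / h
    }
    J
  }

  starts <- list(start)
  if (fctrl$multi_start > 0) {
    if (!requireNamespace("lhs", quietly = TRUE))
      stop("multi-start requires the 'lhs' package", call. = FALSE)
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(fctrl$seed)
    H <- lhs::randomLHS(fctrl$multi_start, length(free))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
    for (s in seq_len(fctrl$multi_start)) {
      p <- bounds$lower + H[s, ] * (bounds$upper - bounds$lower)
      names(p) <- free
      starts[[s + 1]] <- p
    }
  }

  best <- NULL
  for (st in starts) {
    run <- lm_windowed(fn, jac, st, bounds$lower, bounds$upper, fctrl)
    if (is.null(best) || min(run$phi_trace) < min(best$phi_trace))
      best <- run
  }

  par <- best$par; names(par) <- free
  res <- hydrolysis_objective(par, experiments, geom, cond, base_params,
                              control)
  p <- base_params
  for (nm in intersect(free, c("k_a", "k_b", "k_d", "alpha")))
    p[[nm]] <- unname(par[[nm]])
  params <- kinetic_params(p$k_a, p$k_b, p$k_d, p$alpha)
  per_species <- tapply(as.numeric(res)^2, experiments$species, sum)
  structure(list(params = params, par = par, free = free,
                 Phi = attr(res, "Phi"), residuals = as.numeric(res),
                 experiments = experiments,
                 per_species_Phi = per_species,
                 iterations = best$iterations,
                 termination = best$termination,
                 phi_trace = best$phi_trace,
                 converged = best$termination == "phi_improvement"),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>\n  free parameters:\n")
  for (nm in x$free) cat(sprintf("    %-8s = %.6g\n", nm, x$par[[nm]]))
  cat(sprintf("  Phi = %.6g (yield-%%^2, %d observations)\n", x$Phi,
              length(x$residuals)))
  cat(sprintf("  %d LM iterations, termination: %s\n", x$iterations,
              x$termination))
  invisible(x)
}

#' Write a fit report to JSON and a residual table to CSV
#'
#' @param fit A [fit_kinetics()] result.
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report list.
#' @export
write_fit_report <- function(fit, json_path = NULL, csv_path = NULL) {
  report <- list(
    params = unclass(fit$params), free = fit$free,
    par = as.list(fit$par), Phi = fit$Phi,
    per_species_Phi = as.list(fit$per_species_Phi),
    iterations = fit$iterations, termination = fit$termination,
    phi_trace = fit$phi_trace)
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    tab <- cbind(fit$experiments,
                 model = fit$experiments$yield_pct + fit$residuals,
                 residual = fit$residuals)
    utils::write.csv(tab, csv_path, row.names = FALSE)
  }
  invisible(report)
}

# closed-form ordinary least squares of y on x
ols_line <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c(intercept = yb - slope * xb, slope = slope)
}

#' Arrhenius regression of rate constants on temperature
#'
#' Ordinary least squares of `ln k` against `1/T`:
#' `Ea = -slope * R`, `k0 = exp(intercept)`.
#'
#' @param T_K Temperatures (K), at least two.
#' @param k Rate constants (m^3 mol^-1 s^-1), all positive.
#' @return An [arrhenius_fit()].
#' @examples
#' fit_arrhenius(c(383.15, 398.15, 413.15),
#'               c(2.0630e-4, 5.7028e-4, 1.6667e-2))
#' @export
fit_arrhenius <- function(T_K, k) {
  if (length(T_K) < 2 || length(k) != length(T_K))
    stop("need rate constants at >= 2 temperatures", call. = FALSE)
  if (any(k <= 0)) stop("rate constants must be positive", call. = FALSE)
  if (any(T_K <= 0)) stop("temperatures must be positive (K)", call. = FALSE)
  cf <- ols_line(1 / T_K, log(k))
  arrhenius_fit(k0 = exp(cf[["intercept"]]),
                Ea = -cf[["slope"]] * GAS_CONSTANT)
}

#' Exponential regression of the hard-to-hydrolyse fraction
#'
#' Log-linear least squares of `ln alpha` against `T` (the spreadsheet
#' exponential-trendline convention): `alpha(T) = A exp(-b T)` with
#' `b = -slope`, `A = exp(intercept)`.
#'
#' @param T_K Temperatures (K), at least two.
#' @param alpha Fitted hard-to-hydrolyse fractions, all positive.
#' @return An [alpha_law()].
#' @examples
#' fit_alpha_law(c(383.15, 398.15, 413.15), c(0.32016, 0.17809, 0.05211))
#' @export
fit_alpha_law <- function(T_K, alpha) {
  if (length(T_K) < 2 || length(alpha) != length(T_K))
    stop("need alpha values at >= 2 temperatures", call. = FALSE)
  if (any(alpha <= 0)) stop("alpha values must be positive", call. = FALSE)
  cf <- ols_line(T_K, log(alpha))
  alpha_law(A = exp(cf[["intercept"]]), b = -cf[["slope"]])
}

#' Predict yield curves at an uncalibrated temperature
#'
#' Assembles the kinetic parameters from the fitted temperature laws
#' (three Arrhenius fits plus the exponential alpha law) and runs a full
#' forward simulation -- no fitting. Refused below the validity window of
#' the alpha law, where the exponential form diverges.
#'
#' @param arr_fits Named list of [arrhenius_fit()] objects: `k_a`, `k_b`,
#'   `k_d`.
#' @param law An [alpha_law()].
#' @param T_K Target temperature (K).
#' @param geom A [material_geometry()].
#' @param cond A [conditions()]; its temperature is replaced by `T_K`.
#' @param validity Validity window (K) of the temperature laws.
#' @param dp,furfural Species passed to [yields()].
#' @param control A [solver_control()].
#' @return A `yield_series` data.frame with the assembled
#'   [kinetic_params()] attached as attribute `params`.
#' @export
predict_at_temperature <- function(arr_fits, law, T_K, geom, cond,
                                   validity = c(383.15, 443.15),
                                   dp = 1:6, furfural = TRUE,
                                   control = solver_control()) {
  if (T_K < validity[1] || T_K > validity[2])
    stop(sprintf(paste0("T = %.2f K outside the validity window ",
                        "[%.2f, %.2f] K of the exponential alpha(T) law"),
                 T_K, validity[1], validity[2]), call. = FALSE)
  stopifnot(all(c("k_a", "k_b", "k_d") %in% names(arr_fits)))
  params <- kinetic_params(
    k_a = arrhenius_rate(arr_fits$k_a, T_K),
    k_b = arrhenius_rate(arr_fits$k_b, T_K),
    k_d = arrhenius_rate(arr_fits$k_d, T_K),
    alpha = alpha_of_T(law, T_K))
  cond2 <- conditions(T_K = T_K, C_H = cond$C_H, t_end = cond$t_end,
                      output_times = cond$output_times)
  traj <- simulate_hydrolysis(geom, cond2, params, control)
  out <- yields(traj, dp = dp, furfural = furfural)
  attr(out, "params") <- params
  out
}

#' Write temperature-law fits to JSON
#'
#' Stores both the raw coefficients and the log-space regression
#' coefficients of the three Arrhenius laws and the alpha law.
#'
#' @param arr_fits Named list of [arrhenius_fit()] (`k_a`, `k_b`, `k_d`).
#' @param law An [alpha_law()].
#' @param path Output JSON path.
#' @return Invisibly, the report list.
#' @export
write_laws <- function(arr_fits, law, path) {
  report <- list(
    arrhenius = lapply(arr_fits, function(f)
      list(k0 = f$k0, Ea = f$Ea,
           log_space = list(intercept = log(f$k0),
                            slope = -f$Ea / GAS_CONSTANT))),
    alpha = list(A = law$A, b = law$b,
                 log_space = list(intercept = log(law$A), slope = -law$b)))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
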