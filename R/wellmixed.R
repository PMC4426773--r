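# Zero-dimensional (well-mixed) population balance, written longhand with
# explicit loops over the breakage kernel. Deliberately independent of the
# vectorised PDE right-hand side: it serves as the reference solution that
# the transport solver must reproduce in the fast-diffusion limit.

#' Solve the well-mixed population-balance system
#'
#' Integrates the scission/degradation kinetics alone (no spatial
#' transport): furfural plus chains `1..N` in a single well-mixed volume,
#' with the porosity closure (and hence the effective acid `psi = eps_v
#' C_H`) evolving as solid xylan dissolves. Equivalent to the full model in
#' the limit of fast diffusion and negligible hydrolysate volume.
#'
#' @param geom A [material_geometry()] (supplies `N`, `m`, `F_hat`,
#'   `eps_N0`, `rho_s`; the radial fields are ignored).
#' @param cond A [conditions()] object.
#' @param params A [kinetic_params()] object.
#' @param pore_feedback If `FALSE`, fix `eps_v = 1` (pure kinetics at bulk
#'   acid concentration) instead of the porosity closure.
#' @param rtol,atol Integration tolerances (dense `lsoda`).
#' @return A data.frame: `time_s`, `phi_F`, and `phi_1..phi_N`
#'   (kg m^-3), one row per output time.
#' @export
solve_well_mixed <- function(geom, cond, params, pore_feedback = TRUE,
                             rtol = 1e-10, atol = 1e-12) {
  N <- geom$N; m <- geom$m
  F_hat <- geom$F_hat; eps_N0 <- geom$eps_N0; rho_s <- geom$rho_s
  k_a <- params$k_a; k_b <- params$k_b; k_d <- params$k_d
  alpha <- params$alpha; C_H <- cond$C_H

  rhs <- function(t, y, p) {
    phi <- y[-1]
    eps_v <- if (pore_feedback) {
      1 - (F_hat + sum(pmax(phi[(m + 1):N], 0)) / rho_s + alpha * eps_N0)
    } else 1
    psi <- eps_v * C_H
    d <- numeric(N)
    for (i in seq_len(N)) {
      loss_k <- if (i == 1) k_d else if (i <= m) k_b else k_a
      d[i] <- -loss_k * psi * phi[i]
      if (i < N) {
        for (j in (i + 1):N) {
          k_j <- if (j <= m) k_b else k_a
          d[i] <- d[i] + 2 * k_j * psi * (i / (j * (j - 1))) * phi[j]
        }
      }
    }
    list(c(k_d * psi * phi[1], d))
  }

  y0 <- numeric(N + 1)
  y0[N + 1] <- (1 - alpha) * eps_N0 * rho_s
  times <- cond$output_times
  if (times[1] > 0) times <- c(0, times)
  out <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  out <- as.data.frame(out)
  names(out) <- c("time_s", "phi_F", paste0("phi_", seq_len(N)))
  if (cond$output_times[1] > 0) out <- out[-1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Brute-force oracles for random scission of short chains
#'
#' Two independent solutions of the well-mixed scission system for an
#' initially monodisperse population of chains of length `N_small <= 6` at
#' fixed effective acid concentration `psi`: (a) a dense high-accuracy ODE
#' solve of the small system written out longhand, and (b) an event-driven
#' stochastic simulation of random scission over a large population of
#' chains. Both report mass fractions of the total initial mass (including
#' the unreactive portion), so every row sums to 1 up to Monte-Carlo error.
#'
#' Chains of length `> m_cutoff` scise at `k_a`, shorter ones at `k_b`,
#' monomers degrade to furfural at `k_d`; a fraction `alpha` of the initial
#' chains is unreactive and never breaks.
#'
#' @param N_small Initial chain length (2..6).
#' @param params A [kinetic_params()] object.
#' @param psi Fixed effective acid concentration (mol m^-3).
#' @param t_grid Times (s) at which both solutions are reported.
#' @param m_cutoff Solubility cutoff for the `k_a`/`k_b` split; defaults to
#'   `N_small` (every chain aqueous).
#' @param n_chains Total number of simulated chains (split into batches).
#' @param n_batches Independent batches used to estimate Monte-Carlo error.
#' @param seed RNG seed for the stochastic simulation.
#' @return A list: `ode` (data.frame `time_s`, `furfural`, `X1..XN_small`,
#'   `unreactive`: mass fractions), `stochastic` (same shape, batch means),
#'   `se` (standard errors of the stochastic means).
#' @examples
#' orc <- scission_oracle(2, kinetic_params(0, 1e-4, 0), psi = 51,
#'                        t_grid = c(0, 60, 300), n_chains = 2000)
#' orc$ode$X2  # decays as exp(-k_b * psi * t)
#' @export
scission_oracle <- function(N_small, params, psi, t_grid,
                            m_cutoff = N_small, n_chains = 1e5,
                            n_batches = 20, seed = 1) {
  N_small <- as.integer(N_small)
  if (N_small < 2 || N_small > 6)
    stop("oracle supports initial chain lengths 2..6", call. = FALSE)
  stopifnot(psi >= 0, all(diff(t_grid) > 0), min(t_grid) >= 0)
  k_a <- params$k_a; k_b <- params$k_b; k_d <- params$k_d
  alpha <- params$alpha
  rate_of <- function(j) if (j > m_cutoff) k_a else k_b

  ## (a) longhand ODE on mass fractions, phi_{N_small}(0) = 1 - alpha
  rhs <- function(t, y, p) {
    phi <- y[-1]
    d <- numeric(N_small)
    for (i in seq_len(N_small)) {
      loss_k <- if (i == 1) k_d else rate_of(i)
      d[i] <- -loss_k * psi * phi[i]
      if (i < N_small) {
        for (j in (i + 1):N_small) {
          d[i] <- d[i] + 2 * rate_of(j) * psi * (i / (j * (j - 1))) * phi[j]
        }
      }
    }
    list(c(k_d * psi * phi[1], d))
  }
  y0 <- c(0, numeric(N_small - 1), 1 - alpha)
  tt <- if (t_grid[1] > 0) c(0, t_grid) else t_grid
  sol <- deSolve::lsoda(y0, tt, rhs, parms = NULL,
                        rtol = 1e-11, atol = 1e-13)
  if (t_grid[1] > 0) sol <- sol[-1, , drop = FALSE]
  cn <- c("furfural", paste0("X", seq_len(N_small)))
  ode <- data.frame(time_s = t_grid)
  ode$furfural <- sol[, 2]
  for (i in seq_len(N_small)) ode[[paste0("X", i)]] <- sol[, i + 2]
  ode$unreactive <- alpha

  ## (b) event-driven stochastic simulation, batched for MC error
  batch_size <- ceiling(n_chains / n_batches)
  n_out <- length(t_grid)
  acc <- array(0, dim = c(n_out, N_small + 2L, n_batches))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  for (b in seq_len(n_batches)) {
    n_react <- stats::rbinom(1, batch_size, 1 - alpha)
    counts <- integer(N_small)
    counts[N_small] <- n_react
    furf <- 0L
    total_units <- N_small * batch_size
    t_now <- 0; ptr <- 1L
    repeat {
      a_sc <- numeric(N_small)
      for (j in seq_len(N_small)) if (j >= 2)
        a_sc[j] <- rate_of(j) * psi * counts[j]
      a_deg <- k_d * psi * counts[1]
      a_tot <- sum(a_sc) + a_deg
      t_next <- if (a_tot > 0) t_now + stats::rexp(1, a_tot) else Inf
      while (ptr <= n_out && t_grid[ptr] < t_next) {
        acc[ptr, , b] <- c(furf, seq_len(N_small) * counts,
                           batch_size * N_small - n_react * N_small) /
          total_units
        ptr <- ptr + 1L
      }
      if (ptr > n_out || a_tot == 0) break
      t_now <- t_next
      u <- stats::runif(1) * a_tot
      ev <- findInterval(u, cumsum(c(a_sc, a_deg))) + 1L
      if (ev <= N_small) {              # scission of a chain of length ev
        counts[ev] <- counts[ev] - 1L
        bond <- sample.int(ev - 1L, 1L)
        counts[bond] <- counts[bond] + 1L
        counts[ev - bond] <- counts[ev - bond] + 1L
      } else {                          # monomer degradation
        counts[1] <- counts[1] - 1L
        furf <- furf + 1L
      }
    }
  }
  mean_mat <- apply(acc, c(1, 2), mean)
  se_mat <- apply(acc, c(1, 2), stats::sd) / sqrt(n_batches)
  stoch <- data.frame(time_s = t_grid, mean_mat)
  names(stoch) <- c("time_s", cn, "unreactive")
  se <- data.frame(time_s = t_grid, se_mat)
  names(se) <- c("time_s", cn, "unreactive")
  list(ode = ode, stochastic = stoch, se = se)
}
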