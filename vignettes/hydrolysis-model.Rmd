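---
title: "A population-balance model of dilute-acid xylan hydrolysis: model, numerics and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A population-balance model of dilute-acid xylan hydrolysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical picture

Dilute sulfuric acid hydrolyses the hemicellulose fraction of
lignocellulosic biomass into soluble sugars. `xylanpbm` models this at the
scale of a single idealised cylindrical fibre surrounded by an annulus of
acid solution (the hydrolysate). Hemicellulose is represented as linear
xylan: chains of `1..N` anhydroxylose units, initially all of maximal
length `N` (a monodisperse start, chosen for simplicity). Chains longer
than a solubility cutoff `m` are solid and immobile; chains of length
`<= m` are aqueous, diffuse radially, and keep reacting in the
hydrolysate. Xylose (chain length 1) degrades further to furfural, which
is the terminal species of the model.

Three assumptions are worth making explicit because they shape everything
downstream:

* **Random scission.** Every internal bond of a chain is equally likely to
  break. The per-chain scission rate is first order in the chain's mass
  concentration and in the effective acid concentration, with one rate
  constant `k_a` for solid chains and another, `k_b`, for aqueous chains.
* **A hard-to-hydrolyse fraction.** A temperature-dependent portion
  `alpha(T)` of the hemicellulose is treated as entirely unreactive on the
  hydrolysis timescale. It occupies volume (it enters the porosity closure
  and the yield denominator) but is not a tracked species.
* **Closed, isothermal system.** No mass crosses the outer boundary; the
  acid is in excess and not consumed; temperature is constant.

Water, acetyl chemistry, branched xylan, furfural degradation products and
cellulose/lignin reactions are all outside the model.

## Equations

With `phi_i(r, t)` the volume-averaged mass concentration (kg m^-3) of
chains of length `i` and `phi_F` furfural, the fibre region
(`0 <= r <= R_i`) obeys

```
d(phi_F)/dt = k_d psi phi_1 + (1/r) d/dr ( r D_eff^F d(phi_F)/dr )
d(phi_1)/dt = -k_d psi phi_1 + gains + (1/r) d/dr ( r D_eff d(phi_1)/dr )
d(phi_i)/dt = -k_b psi phi_i + gains + diffusion        (2 <= i <= m)
d(phi_i)/dt = -k_a psi phi_i + solid gains              (m < i <= N)
```

where the gain of species `i` from every longer parent `j` is
`2 k psi Omega_{i,j-i} phi_j` with `k` the parent's class rate. The
hydrolysate (`R_i < r <= R_o`) carries the same equations without solid
chains and with bulk diffusivities. Boundary conditions are zero flux at
`r = 0` (symmetry) and `r = R_o` (closed vessel).

**Breakage kernel.** The kernel is

```
Omega_{i, j-i} = i / (j (j - 1))
```

This is the unique mass-based random-scission closure consistent with the
loss term `-k psi phi_j` and the gain factor 2: summing over all fragments
of a parent `j` gives `sum_{i<j} 2 Omega_{i,j-i} = 1` exactly, so every
scission event conserves mass to round-off. The test suite asserts this
closure for every `j` up to 100.

**Porosity and effective acid.** The conservation-of-volume closure

```
eps_v = 1 - ( F_hat + sum_{i>m} phi_i / rho_s + alpha * eps_N0 )
```

links the void fraction to the remaining solid xylan (`F_hat` is the fixed
lignocellulose volume fraction; `alpha * eps_N0` the unreactive
hemicellulose). The pores are assumed instantly filled with acid at the
bulk concentration, so the catalytic concentration is `psi = eps_v C_H` in
the fibre and `C_H` in the hydrolysate; the acid is not a transported
species. Porosity starts at `1 - (F_hat + eps_N0) = 0.254` and grows
monotonically to `1 - (F_hat + alpha eps_N0)` as solid dissolves.

**Diffusivities.** Chains follow a modified Stokes–Einstein law,
`D_inf(i) = k_B T / (6 pi eta R_h(i))` with hydrodynamic radius
`R_h(i) = 0.676 l sqrt(i)`; inside the fibre a tortuosity factor
`eps_v^3` applies. Furfural uses a fixed bulk diffusivity
(`1.12e-9 m^2/s`). The viscosity `eta(T)` is not specified by the original
study; the package uses a Vogel liquid-water correlation
(`2.939e-5 * exp(507.88 / (T - 149.3))` Pa s), treating the 0.5 wt% acid
as water, and exposes it as a pluggable function argument.

**Yields.** The reported yield of an aqueous species sums its mass over
the hydrolysate nodes with cylindrical weights `r_k dr_k`, divided by the
initial fibre xylan mass `sum_fibre r_k (phi_N(0) + alpha eps_N0 rho_s)
dr_k` — i.e. percentages are of *total* xylan, reactive plus unreactive,
exactly as the experimental HPLC yields are normalised. The index ranges
are implemented literally, interface node included in both sums and zero
weight at the centre node. One consequence the user should expect: because
the printed diffusion equations equilibrate the volume-averaged
concentration across the whole domain, a fully scised, non-degrading
system asymptotes to the hydrolysate's share of the domain cross-section
(about 90.9% at the default geometry), not to 100%; the tests assert this
partition limit computed from the grid.

## Parameters

| Parameter | Meaning | Unit | Default | Why |
|---|---|---|---|---|
| `F_hat` | fixed lignocellulose volume fraction | – | 0.581 | bagasse composition |
| `eps_N0` | initial xylan volume fraction | – | 0.165 | bagasse composition; initial porosity 0.254 |
| `rho_s` | solid xylan density | kg m^-3 | 1500 | typical cell-wall polysaccharide; yields are invariant to it, only the porosity feedback depends on it |
| `N` | maximum chain length | – | 100 | within the expected DP range of hemicellulose |
| `m` | solubility cutoff | – | 15 | oligomers up to ~DP 15 are water-soluble |
| `l` | monomer segment length | m | 0.65e-9 | xylose unit length |
| `R_i` | fibre radius | m | 3.75e-4 | milled-bagasse particle size |
| `hydrolysate_factor` | `(R_o - R_i)/R_i` | – | 2.32 | liquid ~10x fibre volume |
| `C_H` | bulk acid concentration | mol m^-3 | 51 | 0.5 wt% H2SO4, single deprotonation |
| `D_F_inf` | furfural bulk diffusivity | m^2 s^-1 | 1.12e-9 | literature value |
| `k_a, k_b, k_d` | scission/degradation rates | m^3 mol^-1 s^-1 | fitted | calibrated per temperature |
| `alpha` | hard-to-hydrolyse fraction | – | fitted | `alpha(T) = A exp(-b T)` across temperatures |

`alpha` is accepted on the closed interval `[0, 1]`: `alpha = 1` is the
degenerate fully unreactive limit (an all-zero reactive state), which the
constructors and solver handle exactly.

All defaults live in a YAML configuration
(`inst/extdata/default_config.yaml`) mirroring these names; partial files
overlay onto the defaults. Note that a bare `N` is a boolean in YAML 1.1,
so the key must be written `'N'`.

## Numerical scheme

* **Space.** Vertex-centred finite volumes on two uniform sub-grids (100
  fibre + 250 hydrolysate nodes by default) sharing the interface
  coordinate at `R_i`. Faces sit midway between nodes; boundary nodes own
  half-cells; cell measures are exact cylindrical `(r_+^2 - r_-^2)/2`.
  Face diffusivities are harmonic means of the adjacent node values, which
  keeps the flux continuous across the `eps_v^3` jump at the interface.
  Whether the original implementation shared or duplicated interface
  unknowns is not documented; the shared-node choice here is ours.
* **Time.** The porosity closure is substituted algebraically, so the
  semi-discrete system is a closed stiff ODE system (no DAE solver
  needed). It is integrated by BDF (`deSolve::lsode`) with an internally
  generated banded Jacobian. States are packed node-major (furfural,
  aqueous chains, then solid chains per node), giving half-bandwidth
  `2N + 1`: diffusion couples equal species one node over (`N + 1`
  positions), and the porosity dependence of face diffusivities couples a
  mobile species to the neighbouring node's solid chains (up to `2N + 1`).
  Default tolerances are `rtol = 1e-7`, `atol = 1e-10`, configurable.
* **Non-dimensionalisation** is not used; with these tolerances the
  dimensional system integrates accurately, and the conservation and
  grid-convergence tests confirm it.
* **Negative concentrations.** Integrator overshoot below zero is clipped
  to zero inside the reaction terms; a trajectory whose excursion exceeds
  `1e-8` of the initial concentration scale triggers a warning. Yields
  clip at zero on extraction.
* **Interpolation.** Model yields are cubic-spline interpolated
  (`stats::splinefun`, FMM end conditions) to the observation times.

At the default resolution a 360-minute simulation takes roughly half a
minute on one CPU. Mass (tracked species plus the static unreactive pool)
is conserved along trajectories to better than `1e-8` relative.

## Calibration

`fit_kinetics()` is a native bounded Levenberg–Marquardt fitter
(`minpack.lm::nls.lm` underneath) that mirrors the control settings of a
PEST-style Gauss–Marquardt–Levenberg run: equal weights on all
observations; forward-difference Jacobians with relative increment 0.01
and per-parameter absolute lower increment bounds; at most 30 iterations,
terminating early when the relative improvement of `Phi = sum(residual^2)`
over a 4-iteration window drops below 0.005 (iterations are chunked in
fours so the windowed stop can be applied between chunks). Parameters are
bounded below by zero and above by defaults chosen to exclude non-physical
values (rates 1 m^3 mol^-1 s^-1, `alpha` 0.9); the original study's exact
upper bounds and increment floors are not documented, so these are package
defaults, not reproductions. Three fitting regimes are supported: rates
only with `alpha = 0`; rates plus `alpha`; and rates plus bulk
diffusivities (`D_inf`, `D_F_inf`, as constants replacing the
Stokes–Einstein law) with `alpha = 0`. An optional seeded Latin-hypercube
multi-start (default off, matching the original single-run practice)
guards against local minima.

The temperature regressions are closed-form ordinary least squares:
`ln k` on `1/T` (Arrhenius: `Ea = -slope * R`, `k0 = exp(intercept)`) and
`ln alpha` on `T` (the spreadsheet exponential-trendline convention).
On exact-law data both recover the generating coefficients to round-off;
`stats::lm` serves as an independent cross-check in the tests.
`predict_at_temperature()` assembles parameters from the laws and runs a
plain forward simulation; it refuses temperatures below 383.15 K, where
the exponential `alpha(T)` form exceeds 1 and is not meaningful.

One caveat the tests document honestly: the three per-temperature `k_a`
values are far from collinear on an Arrhenius plot (the 125 °C value is
missed by a factor ~2.3 by the fitted line), and `alpha(T)` misses its
middle calibration point by ~19%. The regression *coefficients* are
reproduced to better than 1%; the per-temperature *scatter* is a property
of the data, and tests assert it at its actual magnitude rather than
pretending the laws interpolate.

## Experimental conversions

Raw HPLC concentrations (g/L) convert to yields via the initial xylan mass
`X0 = xylan fraction x dry mass`, the hydrolysate volume (from mass, using
the 25 °C water density 997.047 kg m^-3 — kept as stated even though the
drained hydrolysate is hot), a water-of-hydration correction
`(MW(X_i) - MW(H2O))/MW(X_i)` with `MW(X_i) = 132.115 i + 18.02` g/mol
(the DP-dependent molecular-weight convention is ours; the original
reports only the monomer case), and the furfural factor 132/96. Inside the
model, xylose converts to furfural 1:1 by mass — mass conservation is
exact in the model, and the stoichiometric factor lives only in the
experimental conversion.

## Synthetic data and oracles

No machine-readable experimental dataset accompanies the original study
(the yield curves exist only as figures), so the package generates its own
pseudo-experiments: forward-simulate at known parameters, sample at sparse
times (default 15–360 min, mirroring the 110 °C horizon), apply
`y (1 + e_rel) + e_abs` Gaussian noise, clip at zero, and record the truth
in a sidecar JSON. The defaults (5% relative, 0.2 yield-% absolute) are a
visual match to published scatter, not a calibrated error model — the
original reports no replicates or error bars, so they cannot be validated.
Observation rows follow a fixed canonical species order (furfural,
X1..Xm), making the seeded noise stream locale-independent and the CSV
byte-identical across runs. What the generator deliberately does *not*
emulate: the heat-up artefact of high-temperature runs (non-zero yields at
`t = 0`), replicate structure, and chromatographic detection limits.
Passing recovery tests therefore demonstrate the fitter's correctness on
data that match the model's own error assumptions, not robustness to real
instrument systematics.

Two brute-force oracles validate the kinetics independently of the PDE
solver. `solve_well_mixed()` integrates the 0-D system written longhand
(explicit loops over the kernel). `scission_oracle()` additionally runs an
event-driven stochastic simulation of random scission over >= 1e5 chains
(batched, so Monte-Carlo standard errors come from independent batches)
for initial lengths up to 6, where the dimer case has the closed form
`phi_2(t) = exp(-k_b psi t)`.

The fast-diffusion equivalence test deserves a note: a two-region domain
with realistic composition is *never* equivalent to a single well-mixed
system, because the hydrolysate sees the full acid concentration while the
fibre sees `eps_v C_H` (a 2–3% irreducible gap at realistic porosity). The
single-region limit is therefore realised with near-unit fibre porosity
(`F_hat`, `eps_N0` small) and a thin hydrolysate annulus, where the PDE
solution collapses onto the longhand 0-D solution to ~0.03%, well inside
the 1% assertion.

## Study sizes used by the test suite

Property tests run at reduced sizes chosen as a deliberate trade-off
between coverage and turnaround; the physics is identical at every size.

* Solver behaviour, conservation, monotonicity: `N = 12–30`, grids from
  8+6 to 25+50 nodes.
* Grid convergence: `N = 30`, 40+100 vs 80+200 nodes (yield shift
  < 0.07 pp observed against the 0.5 pp bound).
* Parameter recovery: `N = 12`, `m = 4`, 6+3 nodes, 8 sampling times,
  species furfural + X1–X4; noiseless recovery of all four parameters,
  and a 10-seed study at 5% multiplicative noise (median errors
  asserted: rates within 20%, `alpha` within 0.05). The additive noise
  term is switched off in that study: at 110 °C the furfural yield peaks
  well below 1%, so a 0.2 yield-% noise floor would bury the only signal
  `k_d` has.
* The full-resolution configuration (N = 100, 100+250 nodes) is exercised
  once, by the 110 °C headline simulation.

## Known limitations

* Chains are linear and unbranched; acetyl groups, arabinose substituents
  and furfural's own degradation are not modelled.
* The hard-to-hydrolyse fraction is a static scalar per run — no slow
  second pathway, so long-time tails at low temperature are flattened.
* `alpha(T)`'s exponential form is only valid above ~383 K; prediction
  below the calibrated window is refused rather than extrapolated.
* The solid density `rho_s` and viscosity law are configuration, not
  measurements; yields are insensitive to `rho_s` but the porosity
  trajectory is not.
* Isothermal, isobaric, radial-only transport; no fibre shrinkage or
  reactor-scale effects.
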