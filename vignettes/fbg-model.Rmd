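---
title: "The fbgtwin model: assumptions, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fbgtwin model: assumptions, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbgtwin)
```

## The two-compartment balance model

`fbgtwin` treats a batch fluid-bed granulator as two perfectly mixed
compartments. The *bed* holds the dry solids charge, the binder solids
accumulated from the spray, and liquid water; the *chamber air* holds water
vapor in a fixed dry-air holdup. A lumped wall exchanges heat with both and
with the environment. The six states are three masses (bed water, bed
binder, air water) and three temperatures (bed, air, wall).

The mass balances are bookkeeping: spray water and binder enter the bed at
the spray rate split by the binder solids fraction `w_s`; evaporation moves
water from bed to air; air flow sweeps vapor in at the inlet mixing ratio
`x_in` and out at the well-mixed chamber mixing ratio `x = m_air,w/m_air`.
The energy balances combine enthalpy streams (relative to a reference
temperature `T0`) with constant-UA heat-transfer terms. Two modelling
conventions deserve mention because the energy bookkeeping only closes as a
set:

* The evaporation stream carries the full latent plus vapor-sensible
  enthalpy, `ṁ_evap (λ0 + c_p,wg (T_bed − T0))`, out of the bed *and into
  the air*; the sensible enthalpy of the departing liquid is handled by the
  trailing accumulation terms `−(T − T0) ṁ c_p` of the bed and air balances.
  Evaporative cooling of the bed therefore happens directly, while the air
  is cooled through the bed–air convective term that resupplies the bed.
* The latent heat of vaporization is the constant `λ0` at the reference
  temperature; with the convention above the sensible-enthalpy inventory of
  bed + air + wall changes exactly by the boundary streams (spray in, air
  in, air out, wall loss). This *energy closure* is enforced by tests to
  1e-4 relative on randomized recipes, and is the arbiter for all closure
  choices.

The model deliberately has **no particle-size dynamics**: granule growth,
breakage and PSD are outside its scope, and the moisture trajectory is used
as the scale-independent surrogate of process performance.

## Evaporation closure and the two fitted parameters

Evaporation is a film-transfer expression
`ṁ_evap = k A_p (c_w,sat(T_bed) − c_w)` with

* `A_p = 6 m_solid/(ρ_p θ_p)` — the area of monodisperse, time-invariant
  spheres of size `θ_p` at the true particle density. Neither
  monodispersity nor time-invariance is literally true in a granulation;
  the closure is "wrong but useful" and makes `θ_p` an *effective exchange
  length*, not a sieve diameter.
* `k = k0(θ_p) · η(LOD; θ_e)` — a Ranz–Marshall film coefficient
  (`Sh = 2 + 0.6 Re^1/2 Sc^1/3`, Reynolds number from the superficial
  velocity) throttled by an evaporation efficiency
  `η = min(exp(LOD/θ_e) − 1, 1)`: transfer becomes less efficient as the
  bed dries out, with `θ_e` (in LOD %) setting where the throttle bites.
  η saturates at 1 above `LOD = θ_e ln 2`.
* `c_w,sat(T_bed)` — saturation concentration at the particle surface from
  a Magnus-type (Arden Buck) saturation-pressure fit and the ideal-gas law.
  The Buck coefficients reproduce 611 Pa at 0 °C, 2339 Pa at 20 °C and
  101.3 kPa at 100 °C to well under 1 %, over a validity range of −20 to
  150 °C.

Condensation is excluded (`ṁ_evap ≥ 0`): the model targets
drying-dominated operation, and η is nonnegative by construction.

Both uses of `θ_p` (area and film coefficient) are wired to the single
parameter. Flow sensor biases are absorbed by per-product linear correction
factors `α_spray`, `α_air` (default 1, fitted only on demand and then
frozen).

## Tunable parameters and defaults

| quantity | unit | default | why |
|---|---|---|---|
| `θ_p` | m | fitted (synthetic truth 8e-3) | effective exchange length; see below |
| `θ_e` | LOD % | fitted (synthetic truth 5) | efficiency throttle scale |
| `α_spray`, `α_air` | – | 1 | sensor-bias corrections, per product |
| `λ0` | J/kg | 2.45e6 | latent heat near 20–30 °C |
| `D_w` | m²/s | 2.6e-5 | water vapor in air, ~25 °C |
| `ρ_particle` | kg/m³ | 1500 | typical excipient true density |
| heat capacities | J/(kg K) | water 4186/1900, solids 1100, binder 1300, air 1006, steel 490 | handbook values |
| UA conductances | W/K | pilot: bed–air 500, bed–wall 15, air–wall 25, wall–env 10 | lumped, order-of-magnitude for a ~145 L pilot unit |
| solver tolerances | – | rtol 1e-8, atol 1e-10 (masses), 1e-8 (temperatures) | closure tests at 1e-6/1e-4 need margin |
| gate thresholds | LOD % | 0.279 / 0.664 | configured constants (historical mean + 2 sd); not re-derived here |
| humidity levels | g/kg | 1 / 5 / 10 | dry-season extreme, target, humid extreme |
| σ per parameter | °C, kg/s | 1.0 / 0.01 / 2e-4 | typical controller/sensor scatter at pilot scale |

All property and equipment tables are plain lists the user can override
field-wise (`material_properties()`, `equipment_properties()`).

## What the synthetic generator emulates — and what it does not

`make_recipe` produces a pilot recipe (60 kg charge; 10 min premix, five
10-min spray subphases at 0.009 kg/s solution and 0.45 kg/s air at 60 °C,
two short dry subphases at 65/70 °C ending near 1–2 % LOD) and a 3.6×
scaled commercial variant (216 kg). Wet/target/dry condition variants
rescale the spray rate ±10 % at constant total binder (duration adjusts
inversely). `make_batch` samples a simulated trace (2 premix, 5 spray, 4 dry
samples), jitters the *recorded* sampling times with Normal(0, `time_jitter_sd`)
and adds Normal(0, `noise_sd`) to the LOD values — the two dominant error
sources of manual LOD sampling.

The ground-truth effective particle size is **8 mm**, not a powder-like
200 µm. This is a deliberate fixture choice: with `A_p = 6m/(ρθ_p)` and
Ranz–Marshall `k0`, a 200 µm `θ_p` at pilot scale yields `k0·A_p` of order
500 m³/s — the chamber air then always equilibrates to saturation at the bed
temperature, the trajectory is purely limited by the air's carrying
capacity, and the two fitted parameters have essentially no influence on
the observable LOD trace (they would be unidentifiable from any data). At
8 mm the film term is rate-limiting, both parameters shape the trajectory,
and the simulated traces show the canonical flat–rise–decline shape with a
maximum LOD near 9 % and a bed temperature well below the inlet air during
spraying. Fitted values of an *effective* parameter in industrial practice
similarly absorb all unmodelled area effects (wetted fraction, shielding,
agglomeration) and need not resemble a physical particle size.

Passing tests on these synthetic campaigns demonstrate *self-consistency*:
the estimator recovers the parameters that generated the data, gates behave
as configured, and the scenario/uncertainty machinery is correct. They do
not demonstrate that the two-compartment model describes any particular
real granulator — that evidence must come from calibration and validation
gates on real batch records. Real premix segments are also flatter than the
synthetic ones: the model has no equilibrium-moisture floor, so any initial
free water (the synthetic initial LOD of 1 %) dries off during premix,
whereas bound moisture in real excipients does not.

The product archetypes construct their design spaces from the model itself:
the *robust* archetype brackets the worst-case coordinated 2σ deviations at
both humidity extremes (plus margin), so its whole scenario-set-I
enumeration stays in range; the *sensitive* archetype runs 18 °C colder —
drying capacity close to the spray load makes the maximum LOD strongly
humidity-dependent — and gets a design space narrower than its humidity
swing, so the 1 and 10 g/kg extremes are out of range even with no
disturbance. These mirror the two qualitative robustness profiles seen in
industrial fingerprints.

## Scenario sets and scoring

Set I applies fixed 2σ coordinated deviations for every nonempty
combination of the three deviatable parameters and every nonempty subset of
the five spray subphases (217 scenarios per direction per humidity level;
subsets need not be contiguous). Sets II–IV search an ascending integer σ
grid — (1–30)σ for II, (1–20)σ for III and IV — for the largest magnitude
whose maximum LOD stays inside the design space. The full grid is always
evaluated (no early exit): the response need not be monotone — a too-dry
process can be pushed *into* the design space before leaving it again — and
the integer grid keeps results exactly reproducible. The search reports the
range top when the grid never leaves the space, and flags (rather than
errors on) a nominal run that is already out of range, which genuinely
occurs for sensitive products at extreme humidity.

The *deviation score* of a scenario is (#parameters varying) ×
(#spray subphases affected), a surrogate for improbability. Set III's six
uniformly spaced 5-minute pulses are treated as a single event
(`n_phases_affected = 1`), so its scores are 1–3 — the number of parameters
pulsed — matching how pulsed-disturbance results are conventionally grouped.
"Wet" deviations are sign-coordinated to raise the maximum LOD (more spray,
colder and slower air); "dry" is the exact negation. Inlet-air humidity is
not a deviated parameter: it enters as the level (1/5/10 g/kg) at which
every scenario is run, and feed-forward humidity compensation can be
emulated by supplying a humidity-group recipe function
(`select_recipe_by_humidity`, groups 1–3 / 4–6 / 7–10 g/kg).

## Uncertainty propagation

`sample_parameters` maps Sobol low-discrepancy points (own generator,
Joe–Kuo direction numbers for up to 6 dimensions, 30-bit precision,
optional seeded digital-shift scrambling; validated against an independent
reference implementation) through the inverse-Normal transform and an
eigenvalue square root of the fitted covariance. Unphysical samples (any
nonpositive component) are removed and the sequence is consumed further
until at least `max(n, 500)` samples remain. `propagate_uncertainty`
simulates every sample and takes pointwise empirical quantiles (central
95 % by default; the coverage is a configuration choice, as is the
convergence tolerance on the half-sample band-change metric it reports).

`overall_uncertainty` implements the two-step workflow: run the configured
input-variability scenarios at the point estimate, keep the input sets with
the highest and lowest maximum LOD, propagate the parameter uncertainty for
the nominal and both extremes, and take the pointwise envelope. The result
records the procedure's own caveat: selecting extremes by maximum LOD is a
heuristic, not a proof that no intermediate input set yields a more extreme
band; no brute-force cross-product is run by default.

## Numerical choices

* Phase-by-phase integration with lsoda (stiff multistep), rtol 1e-8, atol
  1e-10 on masses and 1e-8 on temperatures; setpoints are piecewise
  constant, so phase boundaries are integration restarts, not events. The
  chamber-vapor time constant (~4 s) against the bed dynamics (minutes)
  is what makes the system mildly stiff.
* The right-hand side exists twice: a readable R reference (`fbg_rhs`) and
  the compiled C version actually integrated; a test drives both over random
  states and requires agreement to machine precision.
* Two auxiliary states accumulate the exhaust-water and outgoing-enthalpy
  integrals, so the conservation diagnostics measure model/solver
  consistency rather than output-grid quadrature error.
* Tiny solver undershoots of the nonnegative masses are clamped at zero in
  the right-hand side and in the reported trajectory; disturbances that
  drive a setpoint negative are clamped at zero with a single consolidated
  warning (extreme dry-direction searches must not abort).
* Calibration minimizes the pooled residual by Levenberg–Marquardt on
  log-parameters (positivity by construction) with bound constraints and
  five multi-starts — `θ_p` log-spaced across its bounds, `θ_e` alternating
  around its start — to break the `θ_p`/`θ_e` compensation ridge. The
  objective's simulation grid (5 s) matches the generator's, keeping the
  noise-free objective floor at solver tolerance. The covariance is the
  Gauss–Newton approximation `s²(JᵀJ)⁻¹` from a finite-difference Jacobian
  at the optimum (pseudo-inverse fallback if singular).
* Empirical band quantiles use the default continuous quantile estimator;
  permutation-invariance of the band is tested.
* Degenerate inputs: an empty bed is a division error in `loss_on_drying`;
  a recipe without spray subphases is rejected by the scenario builders; a
  zero-width design space is rejected at construction; zero covariance
  collapses sampling onto the estimate.

## Problem sizes used by the shipped checks

The test suite and acceptance script run entirely on synthetic campaigns
generated at run time: conservation closures on 20 randomized recipes,
parameter recovery over 20 seeded noisy batches, scenario set I at one
humidity level per direction (217 scenarios each), σ* searches on reduced
integer grids, and QMC bands at 512 and 1024 samples. These sizes give
stable statistics for every assertion while a full run of the suite stays
in the minutes range on a single CPU.

## Known limitations

* No particle-size evolution, spray-zone/droplet submodel, or PSD output;
  no equilibrium (bound) moisture, so the bed can dry to exactly zero LOD.
* Heat transfer uses constant lumped UA values; radiation and geometry
  effects are absorbed into them, and the wall is a single node.
* The outlet humidity equals the chamber mixing ratio (perfect mixing);
  bypassing and spatial humidity gradients are not represented.
* Sampling-time uncertainty is injected by the generator but not modelled
  in the fit objective (recorded times are taken at face value).
* The acceptance-gate thresholds are configured constants taken from an
  historical multi-product study; the package does not re-derive them.
* The σ* metric reports integer grid values only, by design.
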