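---
title: "Modelling local vancomycin release and distribution: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling local vancomycin release and distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vancoelute)
```

## The physical model

A vancomycin-loaded PLLA coating on a bone plate releases drug into the
surrounding media, where it spreads by Fickian diffusion and is removed by
first-order elimination. The package solves

$$\frac{\partial C}{\partial t} = D \frac{\partial^2 C}{\partial x^2}
  + \frac{\ln 0.5}{t_{1/2}}\,C$$

with an explicit (forward-Euler, central-difference) scheme on cell-centered
grids. Canonical units throughout: length mm, time h, mass µg, concentration
µg/mL; conversions (`convert_diffusivity()`) happen only at the boundary of
the system, because geometries are mm-scale and the clinically meaningful
thresholds (MIC 2 µg/mL, toxicity 1,000 µg/mL) are printed in µg/mL.

Key update rules:

* interior cells: `C_i + (D Δt/Δx²)(C_{i−1} − 2 C_i + C_{i+1})` plus the
  clearance term;
* release-surface cell: gains `(Δt/Δx)·J_in(t)` (in consistent units; with
  µg/mL concentrations this carries a factor 1000 mm³/mL);
* sealed walls: one-sided stencil (zero flux through the face);
* sink (perfect removal): the boundary cell is pinned to 0 *after* the
  stencil update. A general `bc_dirichlet(value)` covers the
  held-concentration boundary needed by the similarity-solution oracle.

In porous bone the diffusivity is the effective value
$D_\mathrm{eff} = D_0\,\delta\,\varphi/\tau$ — constrictivity and porosity
reduce the free-water coefficient, tortuosity (a path-length ratio) divides
it. This is the standard porous-media form; with the packaged structural
parameters (δ 0.84/0.96, φ 0.05/0.95, τ 1.10 for cortical/cancellous) it
gives 1.08×10⁻⁷ and 2.35×10⁻⁶ cm²/s. Configurations may override per-layer
diffusivities directly (`D_mm2_h`) when a user prefers tabulated values over
the relation.

At layer interfaces the face diffusivity is the **harmonic mean** of the two
adjacent cells. This realizes a resistance-free interface with a continuous
concentration and, unlike the arithmetic mean, conserves flux across strong
diffusivity contrasts (cortical/cancellous differ by a factor ~22); the
steady-state interface-flux test asserts this to 10⁻⁶ relative.

## Stability, positivity, and the mass ledger

The explicit scheme is only conditionally stable; steps are validated
against Δt ≤ Δx²/(6D) using the largest diffusivity on the grid, and any
violation raises a typed error (`vanco_stability_error`) before NaNs can
appear. Under that bound the pure-diffusion update is a convex combination,
so concentrations cannot go negative; a post-step guard turns any genuine
negative into a diagnostic solver fault rather than silent clipping
(rounding-level negatives below 10⁻¹⁰ of the field scale are zeroed).

Every run maintains a ledger: cumulative boundary influx, cumulative cleared
mass, net mass exchanged by pinned boundaries, and stored mass. The closure
identity `influx + boundary_net = cleared + Δstored` is exact up to floating
rounding (observed ~10⁻¹⁴ relative) and is asserted at 10⁻⁶ in tests — it
guards the wiring (units, face fluxes, source terms), not the physics.

## Clearance discretization

Two modes are provided. The per-step *increment* form
`Δt·(ln 0.5/t_1/2)·C·0.5^(Δt/t_1/2)` matches the per-element mass-balance
derivation and is the default; the *exact* mode multiplies by
`0.5^(Δt/t_1/2)` after the diffusion update and reproduces exponential decay
exactly at any Δt. The increment form has an O(Δt) bias: over six half-lives
(t½ = 4 h) it overshoots 0.5⁶ by ~1.5% at Δt = 0.04 h and by ~0.36% at
Δt = 0.01 h. The decay-accuracy checks therefore run at Δt = 0.01 h for the
increment form; both modes converge as Δt → 0. "No half-life" scenarios use
an explicit *disabled* flag — a half-life of zero would mean instantaneous
removal, which is not what a missing clearance mechanism represents.

## Oracles

Three independent closed forms validate the solver:

* **erfc similarity solution**: a boundary held at C₀ against an initially
  empty half-space gives C/C₀ = erfc(x/2√(Dt)). Distances are measured from
  the pinned cell's center, which is where the discrete Dirichlet condition
  actually lives. Agreement ≤1% relative where C/C₀ > 0.05.
* **analytic slab release**: a slab sealed on one face releasing to a sink,
  M_t/M_∞ = 1 − Σ 8/((2k+1)²π²) exp(−D(2k+1)²π²t/4L²). Because the sink pin
  sits at the last cell center, the continuous slab the scheme approximates
  ends there: the sink cell is initialized at half the load (the half of its
  volume inside the slab) and the analytic length is L_eff = (n−½)Δx. With
  60 cells the curves agree to 0.13% over Dt/L² ∈ [0.01, 1].
* **2-D continuous point source**: surface density σ = Ṁ/(4πD)·E₁(r²/4Dt),
  with E₁ evaluated by numerical quadrature; agreement ≤3% at mid-radius.

## Scenario assumptions (and what is assumption vs data)

The experimental cumulative-release dataset behind the delivery system is
not published, so the generator stands in for it: a Korsmeyer–Peppas profile
with n = 0.5 (Fickian-controlled) scaled to 95% release at 21 days — an
extended-release, no-burst profile. Drug loading defaults to 100 µg per mm²
of plate footprint, chosen once so the simulated tissue concentrations land
on the reported scale (a peak near 950 µg/mL a few hours post-implantation);
it is a documented assumption, not a measurement.

* *In vitro release*: clearance off, free-water diffusivity, sink boundary.
  The slab length (20.8 mm) is an **effective diffusion length** chosen so
  95% release occurs at 21 days with the water diffusivity; it absorbs the
  topcoat-membrane resistance the model does not represent explicitly.
* *Agar assay*: 3×3 cm source square in a 9×9 cm sheet (4 mm deep), agar
  diffusivity 0.72 mm²/h, clearance off, 24 h horizon. The inhibition area
  counts medium cells at or above the MIC plus the substrate footprint
  (growth is impossible under the substrate; both the simulated and measured
  areas exceed the 9 cm² footprint, implying it is counted). A runtime guard
  rejects domains the MIC front reaches. The printed conversion pair
  0.72 mm²/h / 2.08×10⁻⁶ cm²/s is internally inconsistent (0.72 mm²/h is
  exactly 2.0×10⁻⁶ cm²/s); both are accepted as configuration values — agar
  uses 0.72 mm²/h, human tissue 2.08×10⁻⁶ cm²/s.
* *Rat tibia*: the geometry of the referenced animal study is not printed;
  the model is a 1-D cortical–cancellous–cortical stack (0.7/1.6/0.7 mm,
  documented assumptions) with the dose deposited uniformly in the
  cancellous compartment at t = 0 and a 4-h half-life (the human value, as
  assumed in the study this emulates). The model is linear in dose, so the
  shape of the cortical average — a rise to a peak within hours, then
  exponential decay — is dose-free; the default 1 µg bolus is arbitrary.
* *Human bone plate*: the plate releases toward tissue and bone; the two
  sides are solved as independent 1-D domains splitting the release flux
  (default 50/50 — the split is a config knob because no published value
  pins it). The tissue domain is 3 mm at 0.1 mm resolution; the 10 mm height
  enters only area/volume bookkeeping, since edge effects are omitted. Far
  boundaries are sealed (zero gradient).

## Sensitivity workflow

Each parameter (tissue/cortical diffusivity, half-life, porosities) gets a
multiplicative log-normal prior about its base value; the log-sds are
literature-spread assumptions shipped as a documented table (e.g. half-life
4–6 h → sdlog 0.2). Fifty seeded factors are reduced to the 11 nearest-rank
percentiles 0, 10, …, 100; each modified run is compared with the baseline
and the index is the plain ratio of percent changes. Per output time, output
change is regressed on input change and R² / adjusted R² reported — their
agreement indicates the 11-point design could be thinned to eight.

The output metric is the **near-plate average** (first 1 mm of the relevant
domain) rather than the whole-domain average. In a sealed domain with
spatially uniform first-order clearance, the whole-domain average obeys
`d m/dt = influx − λ m` *independently of D* — every diffusion-coefficient
index would be identically zero. The near-plate region is where infection
risk concentrates and reproduces the expected structure: diffusion
coefficients act negatively (faster spreading lowers local concentration),
the half-life positively, with its index rising from ≈0.07 at 1 h toward the
steady-state limit of 1 by 24 h (at quasi-steady state concentration is
proportional to t½, so the index tends to 1). Parameters of the bone stack
are scored on the bone-side near-plate region, tissue parameters and the
half-life on the tissue side.

## Synthetic data and what passing tests mean

Generators are pure functions of (parameters, seed): noisy cumulative
release profiles (Gaussian noise, running-maximum re-monotonization, [0,1]
clipping), noisy sampled concentration series, and a full fixture suite of
scenario configs at reduced resolution. Parameter-recovery tests close the
loop: a 4-h half-life is recovered within 5% from 5%-noise decay data, and
the release exponent n = 0.5 within 5% at the suite's default 2% noise.

The generators emulate *assay variability only*. They do not emulate
hydroxyapatite binding, perfusion/convection, polymer degradation kinetics,
inter-subject pharmacokinetic variability, or bi-/tri-exponential
elimination — so green tests demonstrate numerical and statistical
correctness of the pipeline under its stated model, not fidelity of that
model to any in vivo system.

## Numerical choices and problem sizes

Default resolutions were picked so each scenario runs in well under a minute
on one core: tissue Δx 0.1 mm, bone Δx 0.5 mm, agar Δx 1 mm (2 mm in the
fixture suite), in vitro slab 52 cells; automatic Δt at 0.9 of the stability
bound, subdivided to land exactly on recording instants. Oracle checks use
40 mm / 400 cells (erfc) and 60 cells (slab); the sensitivity sweeps use a
0.3 mm tissue grid. Tie-breaks and degenerate inputs: zone thresholds are
inclusive for "effective" (C = MIC and C = toxicity both count as
effective); a zero-diffusivity stability query is an error ("time step
unconstrained") rather than infinity; the factor = 1 sensitivity point is
excluded (0/0); non-monotone release profiles are rejected at load rather
than clamped.

## Known limitations

One-dimensional layered geometry (no screw holes, no 3-D plate edges); no
advection or perfusion; no drug–mineral binding; single-exponential
clearance; the release profile enters as a boundary flux, so coating-side
saturation feedback is not modelled. The t-test helper implements the
summary-statistics one-sample test only — the replicate count behind the
measured inhibition area (n = 3) is inferred, since only mean ± sd are
published.
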