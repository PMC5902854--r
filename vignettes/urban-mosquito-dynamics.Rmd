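---
title: "Urban mosquito population dynamics: model, numerics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Urban mosquito population dynamics: model, numerics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aedesfvm)
```

## The model

`aedesfvm` simulates *Aedes aegypti* populations over a city neighbourhood
as two coupled fields on a rectangular domain: the winged phase
$M(x, y, t)$ (mature females, the only mobile stage) and the aquatic phase
$A(x, y, t)$ (eggs, larvae, pupae pooled into one static compartment):

$$\frac{\partial (\psi M)}{\partial t}
  = -\nabla\!\cdot\!(vM) + \nabla\!\cdot\!(D\nabla M)
  + \gamma A\left(1 - \frac{M}{k_1}\right) - (\mu_1 + h_1)\,M,$$

$$\frac{\partial (\psi A)}{\partial t}
  = r\,M\left(1 - \frac{A}{k_2}\right) - (\mu_2 + h_2 + \gamma)\,A.$$

Assumptions worth keeping in mind:

* **Two stages only.** All pre-adult stages share one compartment; male
  adults are ignored (only females disperse, oviposit and transmit).
* **The aquatic phase does not move.** Its equation has no advection or
  diffusion; breeding sites stay where they are. Spatial spread happens
  exclusively through the winged phase, which then re-seeds the aquatic
  phase locally through oviposition.
* **Area support $\psi$.** Each location hosts mosquitoes in proportion to
  $\psi(x,y) \in (0,1]$; the observable quantities — what gets mapped and
  integrated — are $\psi M$ and $\psi A$. Because the update divides by
  $\psi$, the implementation requires $\psi \ge 10^{-6}$ and rejects zero.
* **No climate forcing, no demographic noise.** Rates are constants;
  temperature, rainfall and stochastic extinction are out of scope.

## Parameters

Scalar vital rates (defaults from `biology_defaults()`):

| symbol | meaning | default | unit |
|---|---|---|---|
| $\gamma$ | aquatic → winged maturation | 0.2 | day⁻¹ |
| $r$ | oviposition | 30 | day⁻¹ |
| $k_1$ | winged logistic capacity scale | 25 | density |
| $k_2$ | aquatic logistic capacity scale | 100 | density |
| $\mu_1$ | winged mortality | 0.04 | day⁻¹ |
| $\mu_2$ | aquatic mortality | 0.01 | day⁻¹ |

$k_1, k_2$ act purely as density scales in the logistic brackets and are
treated as dimensionless capacities. Per-region fields: $\psi$
(dimensionless), wind $v$ (m s⁻¹), diffusion $D$ (m² s⁻¹, isotropic by
default with $3.75\times10^{-3}$ inside blocks and $1.25\times10^{-2}$ on
streets/parks/beach), and kill rates $h_1, h_2$ (day⁻¹; $h_2 = 0$ in every
built-in scenario because adulticide spraying does not reach the aquatic
stages).

**Units.** Vital rates are per day while transport coefficients are per
second. The solver keeps a single internal clock in seconds and divides all
day-rates by 86 400; reporting is in days. This convention is forced by the
mixed units of the parameter set and is applied in exactly one place (the
compiled kernel), so there is no double conversion.

With the default rates the spatially homogeneous system has the extinction
state and one positive equilibrium,
$(M^*, A^*) \approx (23.776,\, 97.140)$, computed by
`homogeneous_equilibrium()` via bisection to $10^{-10}$ relative tolerance
and verified in the tests against an independent closed-form reduction.
The local basic reproduction number is
$\gamma r / (\mu_1(\mu_2+\gamma)) \approx 714$ and the linearised growth
rate of a seeded cell is $\approx 2.33$ day⁻¹ — numbers that matter for
interpreting the insecticide scenarios (see *Limitations*).

## Discretisation

The domain is a uniform cell-centred grid; fields are `nx × ny` matrices.
The winged-phase update integrates the PDE over each control volume:

* **Advection**: first-order upwind. The face velocity is the arithmetic
  mean of the two adjacent cells; the face value is taken from the upstream
  cell (at an exactly zero face velocity the mean of the two cells is used —
  a pure tie-break, the flux vanishes there anyway).
* **Diffusion**: two-point central difference with the *harmonic* mean of
  the adjacent diffusivities at the face. The harmonic mean preserves flux
  continuity across the block/street coefficient discontinuities that
  dominate these rasters; the arithmetic mean is available as an option.
* **Time**: forward Euler. Because $\psi$ is time-independent the
  $\partial(\psi U)/\partial t$ form reduces to dividing the right-hand
  side by $\psi$.
* **Boundaries**: per side, either zero-gradient ("closed": no diffusive
  flux, advective outflow carried with the boundary-cell value, zero
  advective inflow) or Dirichlet (a ghost value, default 0 for a sea-facing
  side, entering both flux terms).

**Stability bound.** `stable_dt()` returns
$\mathrm{safety} \times \min_c \psi_c / (\hat v_x/\Delta x + \hat
v_y/\Delta y + \Sigma D_x/\Delta x^2 + \Sigma D_y/\Delta y^2)$ with a
default safety of 0.9 and a 600 s cap for transport-free problems. The
velocity term $\hat v$ sums the *outflow parts of the two opposing face
velocities* and $\Sigma D$ sums the two face diffusivities — the quantities
the update actually uses. On uniform fields this is exactly the textbook
$|v_x|/\Delta x + |v_y|/\Delta y + 2D_x/\Delta x^2 + 2D_y/\Delta y^2$ bound
(e.g. a street cell with $\psi = 0.3$, $|v| = (0.05, 0.15)$ m s⁻¹,
$D = 0.0125$ m² s⁻¹ at $\Delta x = 2$ m gives 2.667 s), but it remains a
positivity guarantee at region interfaces and in locally divergent flow,
where both opposing faces can drain the same cell. Property tests draw 100
random heterogeneous parameter sets and verify positivity under this bound.

**Degenerate inputs and failure mode.** A step that produces NaN or a
density below $-10^{-10}\,\max(1, k_1, k_2)$ aborts with the failing time —
the solver never silently clips an unstable run. Values in $[-10^{-10}, 0)$
(round-off) are clamped to zero between segments.

**Verified numerical properties** (all in the test suite): discrete
conservation of $\int \psi U\, d\Omega$ to $10^{-10}$ over 1000
transport-only steps; elementwise agreement ($10^{-13}$) with independent
loop-coded 1-D and ghost-cell 2-D reference operators; first-order
convergence on smooth advected profiles and second-order convergence to the
analytic heat kernel for pure diffusion; both equilibria are fixed points of
the full solver to $10^{-8}$ per step. One nuance: on a *discontinuous*
top-hat profile the L1 self-convergence rate of first-order upwinding is
theoretically $O(\sqrt{\Delta x})$, not $O(\Delta x)$; the suite asserts the
smooth-profile order near 1 and the top-hat order in the band that theory
actually predicts.

## Scenario presets as the data generator

The package generates its own study conditions; there is no external data.
Four presets reconstruct the studied settings:

* **example1** — generic 200 × 200 m quarter, 3 × 3 blocks, streets with
  wind $(0.05, 0.15)$ m s⁻¹, seed in the lower-left corner.
* **example2** — 500 × 500 m Juiz de Fora city centre: a regular street
  grid of 6 × 3 slots holding 17 building blocks and one central park
  ($\psi = 0.8$); street wind $(-0.1, 0.05)$ m s⁻¹; seed in the park.
* **example3** — same domain plus adulticide: either $h_1 = 7.6$ day⁻¹ on
  the single street corridor flanking the park (variant `one_street`) or
  $h_1 = 0.928$ day⁻¹ on every street (`all_streets`); $h_2 \equiv 0$.
* **example4** — 400 × 400 m Copacabana beach front: 12 blocks, streets,
  and a 50 m beach strip on the sea-facing edge with a Dirichlet zero
  winged density there; day/night periodic wind (sea-breeze in by day,
  reversed at night; beach speeds twice street speeds).

Design choices that were genuinely open, and the decisions taken:

* **Block coordinates.** The real neighbourhoods' block outlines are not
  available as data; the presets use regular street grids with the correct
  block counts and domain sizes, flagged as approximate reconstructions in
  their `provenance` fields. Region areas, not exact outlines, drive the
  integrated totals, so this mainly affects fine spatial patterns.
* **Seed amplitude.** Not independently known; the presets seed
  $M_0 = k_1$, $A_0 = k_2$ inside the seed region and 0 elsewhere
  (configurable). The reduction percentages are ratios of two runs sharing
  the seed and are insensitive to it: a tested tenfold amplitude reduction
  moves the day-42 percentages by under 0.5 points.
* **Day/night windows.** Set to 06:00–18:00 / 18:00–06:00 (configurable);
  only the switch times, not the window lengths, are constrained by the
  two-regime description.
* **Sea side.** The daytime wind has $v_x < 0$ (sea towards city), which
  places the sea on the $x = L_x$ edge; the beach strip and the Dirichlet
  side sit there.
* **Treated corridor.** "One street with its surrounding area" is encoded
  as the full-height street corridor immediately upwind (west) of the park,
  where it intercepts the dominant $-x$ drift from the seeded park.
* **Insecticide timing.** $h_1$ is constant over the whole run; no spray
  schedule is modelled.
* **Grid resolution.** Default $\Delta x = 2$ m. The test suite runs the
  scenario comparisons at the 10 m (50 × 50) tier and the verification
  fixtures at 32–256 cells; `scripts/acceptance.R` uses the 4 m
  (125 × 125) tier. The reduction percentages change by under 0.1
  percentage points between the 10, 5 and 4 m tiers, so the coarse tiers
  are adequate for the integrated quantities.

What the presets do *not* emulate: irregular block geometry, vegetation
heterogeneity inside blocks, temperature/rain-driven rate variation,
mosquito behaviour beyond drift + diffusion, and any coupling to human case
data. Passing tests therefore validate the solver and the scenario logic,
not the calibration of any particular city.

## Determinism

There is no randomness anywhere in the pipeline: identical configurations
produce bit-identical totals (asserted in the tests). Wind switches and
snapshot times partition the run into segments; within a segment the step
size divides the segment length exactly, so output times are hit exactly
rather than interpolated.

## Limitations

* **Endpoint insensitivity of the insecticide comparison.** With the
  default vital rates, any cell that receives even a trace winged
  population grows to the local equilibrium within days
  ($R_0 \approx 714$, growth $\approx 2.33$ day⁻¹), and street transport
  (0.1 m s⁻¹ ≈ 8.6 km day⁻¹) seeds the whole domain almost immediately. By
  day 42 both the untreated and the treated runs have saturated, and
  because blocks ($\psi = 1$, ≈ 79 % of the area) dominate the integrals
  while only streets are sprayed, the day-42 reductions computed by
  `scripts/acceptance.R` are small: ≈ 0.5 % (winged) and ≈ 0.03 %
  (aquatic) for all-street spraying, ≈ 0.7 % / 0.02 % for the concentrated
  corridor. Street-level adulticide at 0.928 day⁻¹ cannot flip streets into
  net sinks (their with-kill $R_0 \approx 29$ is still far above 1), so
  large *endpoint* reductions are impossible in this parameter regime —
  they would require the invasion to still be in progress at the evaluation
  time, i.e. substantially slower vital dynamics or much shorter horizons.
  Users comparing strategies in this regime should look at the transient
  window (first days after seeding) or at time-integrated exposure rather
  than endpoint totals.
* **First-order advection.** Upwinding adds numerical diffusion of order
  $v\Delta x/2$; sharp plume edges smear. The integrated totals are robust
  to this (see the resolution sweep above), but fine-grained density maps
  at coarse tiers are diffusive.
* **Forward Euler cost.** The CFL bound ties the step to the finest cell
  and strongest wind (≈ 3 s at $\Delta x = 2$ m), so 42-day runs at the
  default resolution take roughly a million steps; the compiled kernel
  makes this minutes, not hours, but implicit integrators are deliberately
  out of scope.
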