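---
title: "Deconvolving vascular remodeling contributions to pulmonary arterial pressure and impedance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving vascular remodeling contributions to pulmonary arterial pressure and impedance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsedecon)
```

## The question the package answers

Pulmonary hypertension (PH) remodels the pulmonary arterial tree in
several ways at once: the small distal vessels narrow and rarefy
(raising distal resistance), the vessel walls stiffen both proximally
and distally, and the right ventricle ejects a smaller stroke volume.
All three changes push the main pulmonary artery (MPA) pressure
waveform in overlapping directions, so a measured rise in pulse
pressure cannot, by itself, be attributed to any one mechanism.
`pulsedecon` builds an in-silico copy of the pulmonary circulation,
calibrates it to a control hemodynamic state, and then switches the
remodeling mechanisms on one at a time — hypothetical states that
cannot exist in an animal — to quantify each mechanism's isolated
contribution to MPA pulse pressure (ΔMPA pressure) and to the
impedance indices Z0 and Zc.

## Model components

### Wall constitutive model

Each vessel wall is a single-layer, incompressible, hyperelastic
Holzapfel–Ogden material with one symmetric pair of fiber families at
±β from the vessel axis. With principal stretches
(λr, λθ, λz) and the fiber invariant

α = λθ² cos²β + λz² sin²β − 1,

the deviatoric Cauchy stress is the trace-free part of

s_rr = c λr²,
s_θθ = c λθ² + 4 k1 α e^{k2 α²} λθ² cos²β,
s_zz = c λz² + 4 k1 α e^{k2 α²} λz² sin²β,

so that, in particular, σ̄θθ − σ̄rr = c(λθ² − λr²) +
4 k1 α e^{k2 α²} λθ² cos²β. The total stress is σ = p I + σ̄ with the
hydrostatic pressure p fixed by boundary conditions. Parameters: c
(ground-matrix stiffness, kPa), k1 (fiber stiffness, kPa), k2
(dimensionless exponent), β (degrees from the longitudinal axis).

The fiber term is active only in tension (α > 0) by default — the
usual convention for collagen-dominated stiffening; the switch is
exposed (`tension_only`) because inflation-dominated loading keeps
α > 0 in any case. This switch makes the pressure–area relation's
slope discontinuous at the reference area, which several numerical
choices below accommodate explicitly.

### Pressure–area (tube) law

Integrating radial equilibrium through the deformed wall,
P = ∫ (σ̄θθ − σ̄rr)/r dr from the inner to the outer radius, with the
through-wall stretch field given by wall incompressibility at fixed
axial stretch. The integral uses 16-point Gauss–Legendre quadrature in
the reference radial coordinate; doubling the order changes the result
by < 1e−8 relative. Because the stress is linear in (c, k1) at fixed
stretch, the whole law is homogeneous of degree 1 in (c, k1): scaling
both by S_p scales pressure by S_p, which is exactly how proximal
stiffening scenarios are built. We take λz = 1 during inflation (no
reported axial prestretch; configurable), and the reference radius of
every segment is its zero-transmural-pressure radius.

Wall thickness is specified as a ratio h0/r0 (default 0.10) rather
than per vessel, since per-segment thickness is rarely measured;
hypertensive wall thickening can be expressed by raising the ratio.

### 1D flow and the coupled simulation

On every segment the cross-section-averaged mass and momentum balances

∂A/∂t + ∂Q/∂x = 0,
∂Q/∂t + ∂(Q²/A)/∂x + (A/ρ) ∂P/∂x = −(2π ν r/δ)(Q/A),

are closed by the tube law P(A), with boundary-layer thickness
δ = √(νT/2π). Defaults ρ = 1.055 g/cm³ and ν = 0.046 cm²/s are
standard blood properties; all directional conclusions below are
insensitive to them. The scheme is the two-step (Richtmyer)
Lax–Wendroff method on the conservative form, with the pressure term
folded into the momentum flux through B(A) = (1/ρ)∫ A dP (valid
because segments are untapered).

Boundary conditions are imposed in conservative half-cell form: each
boundary node owns a half cell whose inner flux is the scheme's
half-step flux and whose outer flux is prescribed (root inflow) or the
solve unknown (junctions, terminals). Junctions enforce flow
continuity and a common pressure; terminals couple to a three-element
Windkessel (R1, Cd, R2 with R1 = R2) integrated by implicit Euler, or
to a pure resistance when Cd is infinite. Each closure reduces to one
monotone scalar equation, solved by warm-started Newton iteration with
bisection fallback to a flux residual below 1e−17 m³/s, so the
junction mass defect stays below 1e−10 mL/s at every step and the
per-cycle inlet volume balances the summed outlet volumes to ~1e−7 of
the stroke volume once periodic.

Two earlier design iterations are worth recording as warnings to
future maintainers. First, pressure and momentum-flux lookup tables
must have mutually consistent interpolation slopes: building dP/dA by
finite differences at table-cell resolution biased the steady
friction-drop benchmark by 21%. The tables are therefore built on an
8× finer grid, with the reference area aligned to a table node
(because of the tension-only kink) and B computed by parts
(∫A dP = AP − ∫P dA) so no numerical derivative crosses the kink.
Second, characteristic-extrapolation boundary closures — the common
choice in this scheme family — are not mass-conservative at boundary
nodes; they leaked ~3×10⁻⁴ of the stroke volume per cycle on a
5-generation tree, independent of grid resolution, which motivated the
conservative half-cell formulation.

The time step is set from a CFL bound (default Courant number 0.5)
using table wave speeds over the working area range and an advective
estimate that splits the peak inflow down the tree by lumen area; a
runtime check aborts (and the wrapper retries with a halved step) if
the bound is ever exceeded. Cycles repeat from rest (reference areas,
zero flow, zero Windkessel pressure) until the pressure field changes
by less than `periodicity_tol` (relative L2, default 1e−4) between
cycles. An optional conservative second-difference filter
(`eps_filter`) can damp odd-even grid modes; with the conservative
boundary closures it is unnecessary and off by default.

### Parameter estimation from uniaxial tests

Arterial strips tested uniaxially along the circumferential and
longitudinal directions give 2nd-Piola–Kirchhoff stress against
Green–Lagrange strain. For a stretch λ imposed in one direction, the
two lateral Cauchy stresses vanish; with incompressibility this
determines the hydrostatic pressure and the free lateral stretch
(solved by safeguarded bisection — the residual is monotone), and the
model stress follows. `fit_constitutive()` minimizes the summed
squared misfit of both directions jointly (equal per-point weights)
with Levenberg–Marquardt from 12 Latin-hypercube starting points
(fixed seed, so the fit is reproducible), with bounds c ∈ (0, 10³]
kPa, k1 ∈ [0, 10⁴] kPa, k2 ∈ (0, 10²], β ∈ [0°, 90°]. On noiseless
synthetic curves the generating parameters are recovered to ~10⁻⁵
relative; β = 45° is the isotropy point of the two directions, so
identifiability of β degrades only there.

The summary metrics mirror standard reporting for such tests:
`stiffness_at_strain()` (slope at 60% Green strain, from a local
quadratic fit over the 5 nearest samples) and `peak_stress()` (stress
at 50% stretch, i.e. Green strain 0.625).

### Impedance analysis

`impedance_spectrum()` Fourier-transforms one period of pressure and
flow and forms Z(ω) = P̂(ω)/Q̂(ω) at each harmonic of 1/T. Z0 is the
0 Hz value (mean pressure over mean flow); Zc is the mean of |Z| over
0 < f ≤ 250 Hz. Magnitude averaging keeps Zc real and is the
convention in the pulmonary-impedance literature. Harmonics where
|Q̂| falls below 1e−6 of the first harmonic are masked to avoid
dividing by spectral nulls of the flow. Following the pulse-pressure
convention, the diastolic baseline is subtracted from pressure before
transforming; this moves only the 0 Hz term, so Zc is identical under
both conventions while Z0 under full pressure exceeds Z0 under pulse
pressure.

### Synthetic data generators

No vascular geometries, test curves, or flow recordings are shipped;
all inputs are generated:

* `generate_tree()`: self-similar binary trees. Defaults emulate a rat
  pulmonary tree: root (MPA) radius 0.13 cm, root length 1 cm,
  per-generation radius ratio 0.79 (near the symmetric Murray value
  2^(−1/3) ≈ 0.794), child length = 6 × radius, sibling asymmetry
  0.15, five generations (63 segments). Real trees have hundreds of
  vessels over many more generations; 4–7 generations preserve the
  generation-wise pressure-drop structure while keeping a simulation
  in seconds, which is why passing tests on these trees demonstrate
  mechanisms and orderings, not subject-specific magnitudes.
* `apply_ph_remodeling()`: sibling-pair pruning (each event removes a
  terminal pair and re-terminates the parent) plus multiplicative
  narrowing of radii below a threshold — the rarefaction/narrowing
  signature of PH morphometry.
* `generate_uniaxial_data()`: an independent oracle for uniaxial
  stress–strain curves. It minimizes the strain energy over the free
  lateral stretch (equivalent to the zero-lateral-stress conditions)
  and differentiates the energy numerically; it shares no stress code
  with the wall-mechanics module, so its agreement with
  `uniaxial_response()` (< 1e−6 scaled, tested) is a genuine
  cross-check, and fitting data it generates is a genuine inverse
  problem. Optional multiplicative Gaussian noise (default suggestion
  2%) emulates load-cell error.
* `generate_inflow()`: half-sine ejection pulse, zero during diastole
  (no regurgitation), discrete cycle volume exactly the stroke
  volume. Defaults: 300 bpm and 0.33 mL stroke volume (cardiac output
  ~99 mL/min, a typical healthy rat); ejection occupies half the
  cycle, since rat systole lasts roughly 100 ms of a 200 ms beat.

Every generator is a pure function of its configuration and seed.

## Calibration and the scenario matrix

`calibrate_baseline()` matches the simulated MPA mean pressure and
pulse pressure to measured targets by adjusting the total distal
resistance (allocated over terminals ∝ r⁻³, Murray-consistent, each
terminal getting R1 = R2; equal-split selectable) and a uniform distal
stiffness S_d = 1/Cd. Mean pressure is essentially linear in total
resistance; pulse pressure responds to compliance; the two
one-dimensional problems are alternated with secant updates in log
space until both match to 0.1%.

Two observables are required because two parameters are identified; a
pulse-pressure target alone cannot pin down both. Note a structural
property of the R1 = R2 Windkessel: the distal compliance sits behind
R1, so no amount of compliance can filter the pulse below roughly
(Q_peak − Q_min)·R_total/2 on a compact tree. At a mean of 17 mmHg and
control cardiac output this floor is ≈ 24 mmHg, so the package's
default control state is ΔMPA = 26 mmHg at mean 17 mmHg — inside the
compliance-sensitive band. Unreachable targets are reported as an
explicit error carrying the achieved bracket.

The scenario matrix (`build_scenario_matrix()`) contains control;
control with hypertensive (lower) flow; proximal-stiffness-only;
distal-stiffness-only; combined stiffness (↑S: S_p and S_d together);
distal-resistance (↑R_d); stiffness + resistance; and the full
hypertensive state with hypertensive flow. The hypertensive scale
defaults — R_d × 3, S_p = S_d × 2, stroke-volume ratio 0.75 — follow
the direction and rough magnitude of reported PH changes in rats
(PVR roughly tripling, ex-vivo stiffness roughly doubling, stroke
volume falling by about a quarter); every scientific conclusion the
package asserts is an ordering that holds across seeds and ±25%
perturbations of these scales, not a magnitude tied to them.
`interaction_index()` quantifies non-additivity:
I = (combined − baseline) − Σ(single − baseline).

## What the tests establish (and what they do not)

* Exact identities: deviatoric trace, the neo-Hookean closed form
  c(λ² − 1/λ) at k1 = 0, the β = 45° symmetry of the two uniaxial
  directions, tube-law monotonicity and inversion, S_p homogeneity.
* Verification against independent references: the steady
  friction-drop formula on a near-rigid tube (< 1%), the Windkessel
  limits P = Q(R1+R2) (< 0.5%) and Z(high f) → R1 (< 5%), the
  thin-wall Laplace estimate (< 3%), an independent energy-based
  uniaxial oracle (< 1e−6).
* Conservation: junction mass defect < 1e−10 mL/s at every step;
  periodic-cycle volume balance < 1e−6 of stroke volume on a
  5-generation tree.
* Inverse problems: constitutive parameters recovered from synthetic
  curves to 2% (k2 5%); Windkessel calibration round-trips forward
  targets to 2%.
* Directional findings on calibrated synthetic trees (3 seeds, ±25%
  scales): distal resistance dominates the ΔMPA-pressure and Z0
  increases; stiffness dominates the Zc increase; lower hypertensive
  flow alone lowers ΔMPA pressure; the full state is super-additive
  (nonzero interaction).

Problem sizes used by the test-suite and acceptance runs: trees of 2–5
generations (7–63 segments), 25-point uniaxial curves, 512 output
samples per cycle. These are the package's chosen desk-scale study
conditions. What passing them does **not** show: subject-specific
magnitudes (real μCT geometries with hundreds of vessels, measured RV
outflow shapes, per-animal parameter spreads), viscoelastic or
actively contracting walls, vessel taper, or 3D flow features such as
vorticity and wall shear stress — all outside the model class.

## Known limitations

* Single-layer wall; no residual stress or opening angle; β is an
  effective angle, not a histological measurement.
* Reference radii are treated as the zero-pressure configuration; if
  geometry is measured at a working pressure the radii carry that
  bias.
* The R1 = R2 constraint couples the achievable pulse-pressure range
  to total resistance (see the calibration section); relaxing it
  changes the floor but is outside the reported model.
* Windkessel states start at zero pressure, so runs with long
  R2·Cd time constants need tens of cycles to become periodic; the
  periodicity residual is reported and a non-periodic run is flagged
  rather than silently accepted.
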