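---
title: "Modelling epicardial pulsed-field ablation near a stented coronary artery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling epicardial pulsed-field ablation near a stented coronary artery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The physical problem

Epicardial pulsed-field ablation (PFA) places a saline-irrigated
multi-electrode device on the fat layer covering the heart and delivers
trains of sub-millisecond kilovolt pulses. Cells exposed to a field above an
irreversible-electroporation threshold (1000 V/cm for cardiac tissue) die
non-thermally; the clinical targets are the ganglionic plexi buried in the
epicardial fat. The left circumflex coronary artery often runs directly
beneath the ablation site, and that vessel may carry a metal stent. Blood is
roughly twenty times more conductive than fat, and stent steel some eight
orders of magnitude more, so both objects distort the field around them.
`pefsim` models a 2D cross-section of this situation — device, saline film,
fat, myocardium, cardiac blood pool, and an optional artery with and without
a 100 µm stent wall at 0.25 or 1 mm below the electrode — and asks two
questions: does the artery/stent change the lesion (the "PEF-zone", the
region above 1000 V/cm), and does the field distortion cause meaningful
Joule heating?

# Governing equations

The electrical problem is quasi-static conduction,

$$\nabla\cdot(\sigma\,\nabla\phi) = 0,\qquad \mathbf E = -\nabla\phi,
\qquad \mathbf J = \sigma \mathbf E,$$

solved per time instant: capacitive effects and membrane-charging
transients are neglected at these pulse widths. The conductivity of the
cellular media (fat, myocardium, blood) switches from a low-frequency,
intact-membrane value $\sigma_0$ to a high-frequency, porated value
$\sigma_1$ through a sigmoid in the local field magnitude, with a +2 %/°C
temperature factor shared by all aqueous media (saline included):

$$\sigma(E,T) = \Big[\sigma_0 +
\frac{\sigma_1-\sigma_0}{1 + 10\,e^{-(|E|-58000)/3000}}\Big]\cdot
1.02^{\,T-37},\qquad E\ \text{in V/m},\ T\ \text{in °C}.$$

The printed form of this exponent omits the division sign; the reading
$\exp(-(|E|-58000)/3000)$ is the only one for which $\sigma\to\sigma_0$ at
low field and $\sigma\to\sigma_1$ at high field, and is used here.

Heat transport is the bioheat equation with the metabolic and perfusion
terms dropped (both negligible on a 12 ms timescale),

$$\rho c\,\frac{\partial T}{\partial t} = \nabla\cdot(k\nabla T) +
\sigma|\mathbf E|^2 ,$$

with the Joule source active only while a pulse is on.

# Geometry and boundary conditions

The domain is an 80 × 40 mm rectangle: a 0.5 mm saline film, the fat layer,
2.7 mm of myocardium and the cardiac blood pool below. The device footprint
is 3.98 mm; the metal electrode is a 2.56 mm strip with a central 0.76 mm
irrigation hole (two 0.90 mm metal segments, 0.2 mm tall) sitting on the
fat surface. Because the electrode is fully embedded in the saline film,
saline — not catheter polymer — flanks the metal segments; the polymer cap
sits above them. This matters: the saline at the electrode sides feeds the
film laterally and controls how far the lesion spreads.

Electrically, the metal electrode is an equipotential at the pulse voltage
(Dirichlet on every node of the metal region), the bottom edge is the
dispersive pad at 0 V, and every other exterior edge carries zero normal
current. Thermally, the blood pool and (flowing) artery lumen are not
meshed into the heat solve; they act through convective film conditions:
1417 W/m²K at 37 °C on the endocardial wall, 63.19 W/m²K at 37 °C on the
artery wall — applied at the stent inner wall when a stent is present,
since blood still flows through a stented artery — and 20 W/m²K at 21 °C
against air on the top surface. The film coefficients are inputs taken as
given (they derive from blood-flow correlations outside this model's
scope); the flow assumptions behind them are recorded as provenance
metadata in the scenario configs.

## Two geometry parameters the source leaves open

*Fat thickness.* The cross-section figure labels the fat layer without a
value. The default here is **5.0 mm**: it accommodates the 2.3 mm artery at
the 1 mm gap with margin and is anatomically plausible for epicardial fat
over the atrioventricular groove. The PEF-zone width is strongly and
inversely sensitive to this choice — at 5.0 mm the model yields widths of
roughly 8–9 mm, while at 3.8–4.0 mm it reproduces the published
11-millimetre-scale widths, and at 4.5 mm the published lumen field — so
this parameter dominates any numeric comparison with the published values.
It is exposed in `geometry_config(fat_thickness = )` and covered by a
sensitivity test; it is deliberately *not* fitted to published outputs.

*The irrigated saline film in the heat equation.* The film is continuously
infused coolant, not stationary tissue. If it is kept in the conduction
solve as a static layer, its own Joule heating (σ ≈ 1.4 S/m under a
~10⁵ V/m lateral film field) drives the global temperature maximum to the
film beside the electrode, where it is insensitive to the artery and stent
— inconsistent with the published temperature structure, in which the
maximum tracks the hot spot between electrode and artery. The default
(`saline_flowing = TRUE`) therefore excludes the film from the thermal
solve, with adiabatic tissue interfaces; the static-film variant remains
available for comparison.

# Numerical method

* **Mesh.** A deterministic block-structured triangulation: a graded
  tensor grid whose division lines pass through every material interface,
  with a mapped O-grid (transition band, stent annulus rings, lumen rings
  and centre fan) filling a square cut-out around the artery. Target sizes
  are 0.05 mm at electrode edges and the artery/stent wall, growing to
  2.5 mm at the domain border (standard profile); the stent wall always
  carries at least two element layers. There is no randomised point
  placement anywhere, so meshes — and therefore entire simulations — are
  bit-reproducible.
* **Field solve.** P1 Galerkin stiffness with Dirichlet elimination and
  sparse Cholesky. The σ(|E|) fixed point is Picard iteration with
  adaptive under-relaxation (the damping factor halves whenever the update
  oscillates, which happens for elements sitting on the sigmoid
  transition, and recovers geometrically afterwards), tolerance 10⁻³ on
  the relative σ change, warm-started from the previous pulse's field. The
  Cholesky symbolic analysis is computed once per mesh and reused.
* **Heat solve.** Backward Euler with a lumped mass matrix. Lumping plus
  implicit stepping preserves the discrete maximum principle on this mesh,
  which is what guarantees the *thermal latency* property — the
  temperature maximum cannot drift upward after the last pulse — holds
  discretely and not just in the limit. The system matrix is factorised
  once per distinct time step and reused.
* **Coupling.** The field is re-solved at every pulse onset and again
  whenever any node has drifted more than 0.5 °C since the last solve (the
  only thermal feedback is the +2 %/°C factor; note a *uniform* ΔT scales
  σ everywhere equally and leaves the potential unchanged, so only
  differential heating matters). Steps are 10 µs during the 100 µs-interval
  protocol, 2 µs during the 10 µs-interval one, growing geometrically to
  500 µs across the 10 ms post-train latency window.
* **Outcome extraction.** Per-element fields are recovered to nodes by
  area-weighted averaging *per material* — averaging across the
  fat/myocardium interface would smear the conductivity jump into a
  spurious threshold crossing — and the 1000 V/cm isoline is traced by
  marching triangles (exact for fields that are globally linear). Zone
  width/depth are measured over tissue only (fat + myocardium; the saline
  film and device are excluded, since lesion dimensions are a tissue
  quantity). Hot spots are reported in the vertical band of artery
  diameter width: front = between electrode face and artery top, rear =
  between artery bottom and myocardium.

## Problem sizes

The standard profile produces meshes of roughly 7k nodes (no artery) to
17k nodes (stent at 0.25 mm) and ~220 implicit thermal steps per
100 µs-interval run (~575 for the 10 µs-interval runs); one scenario takes
tens of seconds and the full 10-run matrix a few minutes on one core. The
coarse profile (all sizes ×2.4, used by most of the test suite) runs each
scenario in a few seconds. Mesh- and step-halving checks on the reported
quantities change the lesion width by <2 % and the hot-spot temperature by
<0.01 °C.

# Verification strategy

Every solver component is checked against an independent closed form
before it is trusted in the coupled pipeline (`toy_fixtures()`):

* homogeneous strip and two-layer slab — exact piecewise-linear solutions,
  reproduced to machine precision on exact meshes, including boundary
  currents;
* a conducting annulus in an imposed uniform field — the interior field of
  the analytic three-region series solution (a 5×5 linear system solved in
  the fixture itself); at the stent/fat contrast of ~10⁸ the interior
  field collapses below 10⁻⁴ of the applied field, which is the
  Faraday-cage mechanism that protects the stented lumen;
* an insulated uniformly heated block — ΔT = Q·t/ρc, exact for the
  discrete scheme; and a transient Robin slab against its eigenfunction
  series, within 1 %.

Charge conservation (electrode vs pad current, nodal-reaction form) closes
to ~10⁻⁷ relative on study meshes; the potential respects the maximum
principle (0 ≤ φ ≤ 1000 V) everywhere.

# What the scenario factory emulates — and what it does not

`study_scenarios()` generates the ten study runs (no artery; artery ± stent
at 1 and 0.25 mm; each under 100 µs and 10 µs inter-pulse intervals) from
nothing but the printed parameters, so every pipeline stage is testable
without external data. The model is 2D (an infinitely long electrode): it
describes the mid-electrode plane and cannot show end effects, and
per-unit-depth currents rather than device currents. The stent is a
continuous tube, not a strut lattice — a worst case for shielding and a
best case for wall conduction. The saline film's own temperature field,
vessel-wall tissue, tissue damage integrals, and blood-flow CFD are out of
scope; convection enters only through fixed film coefficients. Passing
tests therefore demonstrate internal correctness of the stated model, not
fidelity to any individual anatomy.

# Known limitations

* The fat-thickness sensitivity described above is the dominant source of
  disagreement with the published lesion sizes; any quantitative use
  should set `fat_thickness` from imaging rather than the default.
* Point temperature values directly at the re-entrant electrode-edge
  corner converge slowly under refinement (a conduction corner
  singularity); hot-spot temperatures a gap-width away from the corner are
  mesh-converged to ~0.01 °C.
* Monopolar rectangular pulses only; no biphasic waveforms, no
  multi-electrode sequencing, and no 1 s-interval clinical pacing (which
  would make thermal effects vanish entirely).
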