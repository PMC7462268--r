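---
title: "The hbocsim oxygen transport model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hbocsim oxygen transport model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hbocsim` simulates steady-state oxygen transport through a synthetic
tumor-bearing microvascular network perfused by blood that carries oxygen in
three pools: dissolved in plasma, bound to hemoglobin inside red blood cells
(RBCs), and bound to a cell-free hemoglobin-based oxygen carrier (HBOC)
circulating in the plasma. Its purpose is to compare, under identical initial
conditions, how top-load and exchange infusions of low-affinity (T-State) and
high-affinity (R-State) polymerized human hemoglobin — or a non-oxygen-carrying
control fluid — change tumor oxygenation, through the clinically analogous
summaries a physiologist would measure: regional blood volume and flow,
tissue hemoglobin concentrations and saturations, oxygen extraction
fractions, the metabolic rate of oxygen consumption, and hypoxic volume
fractions.

This vignette records the model equations, every tunable that matters, the
numerical choices, and the design decisions taken where the problem was
genuinely open. Package-wide units: pressure in mm Hg, length in um,
concentration in uM (1 uM = 1e-3 mol/m^3), volumetric flow in um^3/s,
viscosity in cP.

## Oxygen in blood

Each oxygen-binding species is a Hill carrier: fractional saturation
$Y(p) = p^n / (p^n + P_{50}^n)$, with $P_{50}$ the half-saturation pressure
and $n$ the cooperativity. The binding is treated as locally equilibrated —
oxygen off-rates are fast relative to vascular residence times — so no
kinetic state is stored anywhere. The shipped carriers are murine RBC Hb
($P_{50} = 42.1$ mm Hg, $n = 2.2$), human RBC Hb (29.3, 2.9), 35:1 T-State
PolyhHb (34, 1) and 30:1 R-State PolyhHb (1.3, 1).

Whole-blood oxygen content sums the three pools:

$$C_{O_2}(p) = \alpha_{pls}\,p \;+\; HCT \cdot C_{Hb,RBC}\,Y_{Hb}(p)
  \;+\; C_{HBOC}\,Y_{HBOC}(p),$$

with plasma solubility $\alpha_{pls} = 1.71$ uM/mm Hg. The heme
concentration inside RBCs is not a printed constant anywhere we could find;
we default to $C_{Hb,RBC} = 21{,}100$ uM, which follows from a mean
corpuscular hemoglobin concentration of 0.34 g/mL at 64,450 g/mol per
tetramer with four hemes. Every RBC term scales linearly with it, and it is
exposed in `blood_composition()`. HBOC doses stated in mg/mL convert to heme
molarity at 64,500 g/mol per tetramer, four hemes
(`hboc_heme_concentration()`).

The derivative $\kappa(p) = dC_{O_2}/dp$ (the oxygen *capacitance*) controls
how fast vascular pO2 falls as oxygen leaves the blood; it peaks at the Hill
inflection $P_{50}\,((n-1)/(n+1))^{1/n}$, about 27 mm Hg for mouse blood.

A useful scalar comparison is the per-heme delivery deficit of one carrier
against another over the arteriolar window 50–100 mm Hg (the span of the
inlet boundary model below): T-State PolyhHb releases about 45% less oxygen
per heme than murine RBC Hb over that window, R-State about 96% less.

## Synthetic networks and the tumor phantom

Full tumor-growth simulations produce vascular networks whose statistics
(elevated tumor microvascular density and blood volume, a necrotic core,
host tissue periphery) are what the oxygen model actually consumes. The
generator reproduces those statistics directly at desk scale
(~10^2–10^3 segments) instead of growing them:

* arterial and venous trees grow from boundary roots over a cubic lattice by
  seeded randomized expansion until the lattice is claimed, so the two trees
  interdigitate;
* capillaries are lattice edges joining opposite trees; since only
  root-to-capillary paths survive dead-end pruning, the capillary count is
  bisected until total vessel length per volume meets the target
  microvascular density (default 250 mm/mm^3);
* radii follow Murray's law ($r^3$ additive) up the trees from a 3.5 um
  capillary radius.

Root placement presets (`corners`, `faces`) let users emulate peripheral vs
proximal/distal supply configurations, the axis along which tumor position
relative to feeding vessels drives outcomes. Generation is a pure function
of (configuration, seed).

The tumor phantom (`apply_tumor_phantom()`) relabels and dilates segments
inside a tumor sphere (default dilation 1.3), sprouts extra capillary
connections between nearby nodes in the viable shell (emulating angiogenic
densification; default 25% of available pairs), randomly prunes segments in
the necrotic core (default 30%), and builds the tissue phase grid:
`phi_necrotic = 1` in the core, `phi_tumor = 1` in the shell,
`phi_normal = 1` outside. Per-voxel consumption maps follow
$V_M = \phi_N V_{M,host} + \phi_T V_{M,tumor}$ — necrotic tissue does not
consume oxygen — with $V_{M}$ = 45 (mouse host), 15 (human host), 80
(tumor) uM/s, and Michaelis constants 5 (host) and 2 (tumor) mm Hg. The
defaults (480 um domain, 60 um pitch, tumor radius 150 um with a 60 um
necrotic core, 30 um voxels) are the standard desk-scale fixture used by the
tests and the acceptance script.

## Hemodynamics

Steady Poiseuille flow on the graph: segment conductance
$g = \pi r^4 / (8 \mu l)$, node pressures from the sparse linear system
(CHOLMOD), flows from pressure differences. The effective viscosity uses the
empirical diameter- and hematocrit-dependent in-vivo relative viscosity law
(the Fahraeus–Lindqvist effect), which tends to 1 as HCT goes to 0, times
the plasma viscosity. Hematocrit and HBOC are propagated through the
oriented network conserving RBC flux ($Q \cdot HCT$) and HBOC flux
($Q \cdot C_{HBOC}$) at every node; at two-way diverging bifurcations the
RBC flux splits by the empirical phase-separation (plasma skimming) law,
with a flow-proportional fallback (`hct_model = "proportional"`); the HBOC
is plasma-borne and always splits with plasma flow. Because viscosity
depends on hematocrit, pressure solves and partitioning alternate to a fixed
point.

**Boundary feed resistance.** A desk-scale lattice cannot reproduce the
hydraulic resistance of the deep arteriolar trees that real (or
cluster-scale simulated) networks place upstream; with pinned root pressures
the fixture would be over-perfused a hundredfold. Each root is therefore
tied to its pressure (defaults: arterial 60, venous 15 mm Hg) through a feed
conductance representing the truncated upstream/downstream circulation,
calibrated (default 12,000 um^3/(s·mm Hg) per root) so baseline regional
blood flow lands in the physiologic 0.1–0.3 mL/(g·min) range with total
oxygen extraction near 0.6 — the supply-limited regime in which tumor
hypoxia fractions around 50% arise. The feed conductance tracks the
rheological effect of hemodilution (the in-vivo viscosity law at a 50 um
feed radius, scenario hematocrit); the infusate's modest plasma-viscosity
elevation is taken as buffered by upstream autoregulatory tone, with the
vasoactivity of cell-free hemoglobin modeled separately through $k_s$
(below). This is a deliberate design decision: carrying the full infusate
plasma viscosity in the feed instead gives the non-carrying control a ~20%
flow advantage that outweighs the T-State carrier's oxygen carriage and
inverts the T-State-vs-control tumor oxygenation ordering. Users can explore
that regime by wrapping `solve_flow()` with their own feed model.

**Adaptation.** Structural radius adaptation uses a minimal shear-only rule:
$r \leftarrow r\,(1 + \delta\,(k_s S_H - S_{ref}))$ with
$S_H = \log_{10}(\tau + 0.103)$ on the wall shear stress $\tau$ (dyn/cm^2)
and $S_{ref} = \log_{10}(\tau_{ref} + 0.103)$, $\tau_{ref} = 10$ dyn/cm^2 by
default. The multiplier $k_s \le 1$ attenuates the dilatory shear stimulus
to emulate nitric-oxide scavenging by cell-free hemoglobin (1 at baseline
and for controls; 0.96/0.95 for top-load T/R-State; 0.95/0.90 for exchange
T/R-State), driving vasoconstriction. Metabolic and conducted stimuli are
intentionally omitted — the infusion scenarios only manipulate the shear
term. The exact stimulus constants are our own choice (the source of the
simplified adaptation scheme is not in any main text available to us); only
the sign structure and the $k_s$ semantics matter for the comparisons made.

## The coupled oxygen solve

Per segment, vascular pO2 obeys

$$\frac{dP}{dz} = \frac{-2\pi r\, j_{tv}(P)}{Q\,\kappa(P)},
\qquad
j_{tv} = \frac{Sh\, D_{pls}\, \alpha_{pls}\,(P - P_t)}{2r},$$

with the tissue pO2 $P_t$ taken constant along the segment (sampled by
trilinear interpolation at points along the axis and length-averaged). The
vessel radius cancels between the wall area and the flux, leaving a
relaxation toward $P_t$ at rate $\lambda/\kappa(P)$ per um with
$\lambda = \pi\, Sh\, D_{pls}\, \alpha_{pls} / Q$. We integrate with an
exponential (integrating-factor) scheme — each step applies the exact
solution of the locally linearised ODE with the capacitance refreshed at the
step midpoint — which is unconditionally stable, cannot overshoot the tissue
value, and is exact for hemoglobin-free blood. Default step 10 um.

At convergent nodes the mixed pO2 solves the nodal oxygen balance with
flux-weighted hematocrit and HBOC coefficients; the content function is
strictly increasing so bisection on [0, max inlet pO2] finds the unique root
(tolerance 1e-8 mm Hg, which keeps nodal molar imbalance below 1e-8
relative). Boundary inflow segments receive the radius-dependent inlet model
$pO_{2,BC} = \min(p_0 + \Delta\,r,\ p_{max})$ with baseline
$p_0 = 50$ mm Hg, $\Delta = 1$ mm Hg/um, $p_{max} = 100$ mm Hg. Because
flow orientation follows strictly decreasing pressure, a single
descending-pressure sweep visits every node after all its upstream
neighbours; no cyclic flow orientation can arise from a pressure-driven
steady solve.

The tissue field solves

$$\alpha_t D_t \nabla^2 P \;-\; V_M \frac{P}{K_M + P} \;+\; S = 0$$

on the voxel grid with zero-flux (Neumann) outer boundaries. Each segment's
oxygen loss — computed exactly as the content difference
$Q\,(C(P_{in}) - C(P_{out}))$, so the deposited source equals the integrated
wall flux by construction — is splatted onto voxels by length-weighted
trilinear deposition. The Michaelis–Menten nonlinearity is handled by damped
Newton iteration; the linearised systems are symmetric positive definite and
solved by CHOLMOD with the factorisation pattern reused across iterations.
Negative excursions are clamped at zero and counted.

**Outer coupling.** Vascular sweep and tissue solve alternate. A naive
explicit exchange oscillates (small tissue changes swing the segment
transfers by large amounts through the steep Hill capacitance), so each
sweep also deposits the exchange slope
$\partial(\text{transfer})/\partial P_t = Q\,\kappa(P_{out})\,(1 - e^{-L\lambda/\kappa})$
as a Robin-type term in the tissue solve. That term vanishes at the coupled
fixed point — it changes the iteration, not the solution — and makes the
outer loop contract. The tissue field is additionally under-relaxed (default
0.5); convergence requires the largest tissue pO2 change to fall below
0.01 mm Hg (default), typically 20–50 outer iterations on the standard
fixture.

The Sherwood number defaults to the classical constant 3.66 (developed
laminar flow with a uniform wall condition) and may be replaced by a fitted
correlation from the Krogh-cylinder module.

## The Krogh cylinder and Sherwood calibration

`solve_ktc()` resolves a single vessel with Poiseuille (parabolic) axial
convection of whole-blood content, radial diffusion across the lumen, and a
Michaelis–Menten-consuming tissue annulus with a no-flux outer boundary,
marching in z with the radial system solved implicitly at each station
(axial diffusion neglected — the standard parabolic approximation). The
local effective Sherwood number is extracted by inverting the lumped wall
law with the mixing-cup lumen pO2. Two validations anchor it: the
zero-consumption, fixed-wall configuration reproduces the classical
developed value 3.657 within 5%, and the zeroth-order-consumption annulus
matches the closed-form Krogh profile within 1% RMS.

`fit_sherwood()` regresses effective Sherwood numbers from a parametric
sweep on (1/r, HCT, C_HBOC) with an intercept — a stand-in predictor set
chosen on dimensional grounds; constant predictors are dropped
automatically. The fitted `fn` plugs directly into
`transport_params(sherwood = fn)`. On the single-vessel fixture, swapping
the constant 3.66 for a fitted correlation moves total extraction by well
under 20%.

## Infusion scenarios and boundary recalibration

`infusion_scenarios()` ships the seven treatment conditions (baseline;
top-load and exchange of control, T-State, R-State) with their hematocrits
(0.45/0.41/0.35), plasma viscosities, HBOC doses (0/8/14 mg/mL), carrier
affinities and $k_s$ values. `apply_scenario()` produces the post-infusion
blood composition.

Hemodilution reduces the oxygen a unit of blood carries, but the tissue
upstream of the simulated domain still extracts the same amount; blood must
therefore arrive at a lower pO2. `recalibrate_boundary()` enforces this: for
each of 25 radii uniform on [1, 49] um (strictly below the 50 um cap radius,
where the boundary model is informative), it solves
$OE_{baseline}(r) = OE_{post}(p, r)$ for the arrival pO2 by bisection on the
monotone content function (tolerance 1e-6 mm Hg; extraction conservation
holds at every sampled radius to 1e-6 relative before any fitting), then
refits the linear $(p_0, \Delta)$ by least squares with $p_{max}$ held at
100 mm Hg. Identity blood returns the baseline coefficients; any
hemodilution without a carrier lowers $p_0$; the T-State carrier brings some
oxygen along and partially offsets the drop relative to its control. Reference
values for these coefficients depend on the exact RBC heme concentration
and fit domain assumed, so they are treated as directional anchors rather
than exact targets.

## Bulk metrics

Over any region mask (whole domain, tumor = viable shell plus necrotic
core, host, or the viable boundary rim with tumor phase present and
necrotic absent):

* MVD = vessel length per volume (mm/mm^3); RBV = vessel volume fraction;
  RBF = blood inflow crossing into the region per tissue mass at density
  1 g/mL (mL/(g·min)); segment-region intersection by fine sampling along
  each segment (clipped length weighting, verified against a 1 um voxel
  rasterisation oracle within 2%);
* tissue Hb and HBOC heme concentrations and their oxygenated counterparts
  (weighted by local saturation at the segment mean pO2), and the derived
  saturations;
* the species-resolved oxygen extraction fractions from molar flows at the
  domain inlets and outlets (dissolved, RBC-bound, HBOC-bound), whose
  decomposition identity holds to 1e-12;
* MRO2 as the volume-averaged Michaelis–Menten uptake, and hypoxic volume
  fractions below 5 mm Hg computed over non-necrotic tissue only (dead
  tissue mounts no hypoxic response), plus the same fraction over the
  boundary rim.

## What the synthetic fixture does and does not show

The generator emulates the statistics the oxygen model needs — tumor
vascular densification, a non-consuming necrotic core, interdigitated
supply and drainage, seeded determinism — but not the geometry of grown
tumors: no VEGF fields, no vessel regression history, no tortuosity beyond
the lattice, no cohort-scale diversity of bed types, and a feed resistance
standing in for everything outside a half-millimetre box. Passing the
directional checks (exchange dosing raises RBF; T-State exchange oxygenates
the tumor better than its control; the low-affinity carrier releases a far
larger fraction of its oxygen than the high-affinity one; the human
parameterization runs warmer than the mouse) shows the transport model
responds to composition, affinity and perfusion the way the underlying
physiology dictates — not that any particular animal tumor would show these
effect sizes. One known quantitative departure: on this fixture all
infusions *slightly lower* mean tumor tissue pO2 relative to baseline
(the flow gain and the content loss land at a product just below one),
whereas at full cohort scale the same infusions are expected to raise
tumor pO2; the between-treatment orderings are unaffected.

Problem sizes were chosen so a full seven-scenario sweep plus a human
baseline runs in a few minutes on one core: ~450 segments, 16^3 voxels at
30 um, outer tolerance 0.01 mm Hg.

## Reproducibility

Every stochastic step (network growth, capillary selection, phantom pruning
and sprouting) runs under an isolated RNG seeded from the configuration;
identical configuration and seed give byte-identical artifacts, and each run
writes a manifest with the seed, package version and a configuration hash.
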