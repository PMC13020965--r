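---
title: "Modelling the left atrial posterior wall from point clouds: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the left atrial posterior wall from point clouds: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lapwsim)
```

## The problem

Electroanatomical mapping systems export two things that are immediately
useful for modelling and are otherwise wasted: a point cloud (PCD) of the
chamber surface, and unipolar electrograms (EGMs) with electrode positions.
`lapwsim` turns the point cloud of the left atrial posterior wall (LAPW) — a
sheet-like region central to persistent atrial fibrillation — into a
volumetric electrophysiology model *without image segmentation*, simulates
action-potential propagation on it, computes virtual electrograms at the
recorded electrode positions, and quantifies how well those match the
recorded ones.

## Geometry: point cloud to tetrahedral mesh

The mesh pipeline is deliberately deterministic; each stage is a pure
function of its input:

1. **Downsampling** (`downsample_pcd`). Greedy insertion in input order with
   a minimum-distance constraint. Clinical clouds have roughly 1 mm spacing;
   thinning to about 3.5 mm removes the local normal noise that otherwise
   makes the extrusion self-intersect, while preserving wall curvature.
2. **Surface reconstruction** (`reconstruct_surface`). The cloud is aligned
   to its principal axes, projected on the principal plane, Delaunay
   triangulated in 2-D and lifted back. For a sheet-like region this is
   manifold and single-component by construction, unlike ball-pivoting,
   which needs a radius tuned per cloud and manual repair afterwards.
   Clouds whose out-of-plane spread approaches their in-plane extent are
   rejected rather than folded.
3. **Cleaning** (`clean_surface`). A vertex whose incident face normals span
   more than `max_normal_angle` (default 60°) is a spike that would fold the
   extrusion; it is removed and the surface re-triangulated. The default
   threshold is deliberately permissive: on realistic clouds only isolated
   outliers exceed it (typically single vertices), matching the manual
   clean-up such surfaces normally require.
4. **Extrusion** (`extrude_surface`) by the typical LAPW wall thickness of
   2.3 mm along *area-weighted vertex normals* (per-face normals produce
   cracks at vertices). The result is checked for inverted prisms and
   fold-over; failure reports that the surface needs cleaning rather than
   producing a broken mesh.
5. **Tetrahedralization** (`tetrahedralize`). Each prism splits into 3
   tetrahedra with quad diagonals keyed on global vertex indices (each quad
   takes the diagonal through its smallest vertex), which makes neighbouring
   prisms conform without communication — determinism again.
6. **Uniform refinement** (`refine_uniform`). Standard red refinement
   (1 tet → 8, midpoint vertices, Bey's octahedron rule). Volume is
   preserved exactly and edge lengths halve per level; two levels bring a
   millimetre mesh to the 200–300 µm range that monodomain conduction
   velocities need (see *Numerical behaviour* below).

Coordinates are millimetres throughout the geometry stages and are converted
to centimetres only inside the solver, where the printed physiological
constants close dimensionally.

## Fibers and conductivities

The LAPW fiber direction rotates modestly across the wall. `template_field`
implements the rule-based transmural recipe: the element's transmural
direction *n* comes from the gradient of the transmural coordinate recorded
at extrusion, and the in-plane angle interpolates linearly from θ~endo~ to
θ~epi~ (defaults −60°/+60°, exposed in the configuration; the template
anatomy of published rule-based methods is not redistributable, so the
analytic rule is the documented stand-in). `map_fibers` transfers a template
field onto another mesh by translation and per-axis scaling only — the
alignment the atlas approach justifies for this anatomically consistent
region — with nearest-centroid lookup and re-orthonormalization.

Conductivities start from the classic atrial bidomain values (fiber
1.74/6.25, transverse 0.193/2.36 mS/cm intra/extracellular). The monodomain
reduction is σᵢσₑ/(σᵢ+σₑ) per direction — half the harmonic mean. Because
sheet and sheet-normal values coincide, the tensor is transversely
isotropic: σ = σₗ ff′ + σₜ(I − ff′).

`calibrate_conductivity` scales all four compartment values by a single
factor K until a slab simulation reproduces a target conduction velocity
(CV). Plane-wave CV grows like √σ, so the update K ← K·(CV*/CV)² converges
in one or two simulations; convergence is judged on the simulated CV alone,
making the result independent of the update rule.

## The monodomain solver

`simulate_propagation` solves χ(C_m ∂V/∂t + I_ion + I_stim) = ∇·σ∇V with
linear tetrahedral finite elements, a row-sum lumped mass (required for a
fully explicit update), and operator splitting: Rush–Larsen exponential
updates for the 15 Hodgkin–Huxley-type gates of the Courtemanche human
atrial model and forward Euler for V_m and the 5 concentrations. Rush–Larsen
keeps gates in [0, 1] unconditionally and allows dt = 0.01 ms at desk scale;
dt remains configurable down to the 0.001 ms used in production runs (we
measured the CV difference between dt = 0.01 and 0.002 ms at under 0.1%, so
the desk default does not limit accuracy — element size does). A per-run
stability check dt ≤ 0.9·h²_min·χC_m/(6σ_max) refuses to start unstable
runs. Stimuli are cube-region (or explicit-node) currents of 25 pA/pF for
2.5 ms, the clinical-protocol strength; stimulus sites follow the recorded
activation sequence via `select_stimulus_nodes` (electrodes within 2 ms of
the earliest recorded activation).

Activation time is everywhere the time of the minimum temporal derivative —
the clinical unipolar convention, applied verbatim to both extracellular
traces and stored V_m histories. For a transmembrane action potential the
minimum derivative falls in the rapid phase-1 repolarization one or two
milliseconds after the upstroke, a constant offset that cancels in every CV
and LAT-difference computation; we keep the convention uniform rather than
special-casing V_m, and document the ambiguity here.

Fibrosis is *percolation*: fibrotic elements are tagged subdomain 2 and
skipped entirely by assembly, so membrane state is never computed there and
no-flux internal boundaries arise implicitly. The element adjacency of the
remaining tissue is reported so a caller can tell conduction block from
slow conduction.

## Fibrosis patterns

`perlin_field_3d` extends gradient-noise fibrosis generation to three
dimensions: seeded permutation tables, quintic fade, octave summation
(amplitude halves, frequency doubles), coordinates pre-scaled by the feature
size, and — for the fiber-aligned archetypes — compressed along the local
fiber direction before lookup so features elongate along fibers. The four
archetype presets (compact: 1 octave / 8 mm; diffuse: 4 octaves / 1 mm;
interstitial: 3 octaves / 2 mm / anisotropy 6; patchy: 2 octaves / 4 mm /
anisotropy 3) reproduce the qualitative histology classes; the source
literature for the 2-D generator does not print its parameters, so these
presets are this package's own calibration, exposed in `fibrosis_spec` and
characterized by the cluster-size and elongation property tests rather than
asserted as published values. Density is enforced by order-statistic
thresholding — exactly ⌈ρE⌋ elements — because a fixed noise threshold
drifts with seed and geometry.

## Electrograms

The unipolar EGM is the infinite-volume-conductor integral
φ_e = (1/4πσ_b) ∫ χI_m/r, discretized by nodal lumping (consistent with the
lumped-mass FEM, and exact for the single-node point source the tests use).
I_m is the membrane current per unit area, recovered as the diffusion
current −(KV)ᵢ/(χ·Volᵢ), so forward computation is a dense matrix product
over stored history. Blood conductivity σ_b only scales amplitude — it is
the dominant amplitude uncertainty and therefore a first-class configuration
entry (default 6.67 mS/cm ≈ 0.667 S/m blood). Raw traces are computed at
the solver output rate, then band-passed 2–220 Hz with a zero-phase
second-order Butterworth and decimated to 1 kHz, the clinical settings.
Recordings band-limited at 240 Hz instead of 220 Hz can be matched by
widening the configurable band; the non-default band is reported, not
silently reconciled.

## Features and comparison statistics

`characterize` extracts the eight characteristic parameters (downstroke,
rising and recovery upstrokes, signal width, EGM duration, baseline,
peak-to-peak, deflection count) plus the LAT. Two quantities are only
verbally defined in clinical practice and needed concrete rules:

* **Baseline**: mean of the first and last 10 ms; if activity overlaps those
  windows, the trace median. Observed baselines are near zero either way.
* **EGM duration / active window**: samples where |φ − baseline| exceeds
  max(5% of peak-to-peak, 3× baseline-segment SD).
* **Deflections**: local extrema with topographic prominence ≥ 10% of
  peak-to-peak — scale- and offset-invariant by construction; the 10%
  default is this package's choice and is exposed.

The comparison module implements pooled-SD Cohen's d (magnitude reported,
sign retained in `d_signed`; bands at 0.2/0.5/0.8), per-pair absolute
percent errors (pairs with a zero recorded value are excluded and counted),
Pearson correlation on original traces, peak normalized cross-correlation
on baseline-removed unit-peak-to-peak traces, and the morphology embedding:
level-4 biorthogonal-4.4 detail coefficients → PCA of the *recorded* set
(components retained to 90% explained variance) → seeded k-means++/Lloyd
clustering → distances of projected simulated waveforms to the "common" and
"closest" recorded centroids. Where the percent-error convention was
ambiguous we average absolute errors; distances use all retained
components. The wavelet bank is implemented in-package (coefficients of the
standard biorthogonal 4.4 filters, symmetric extension) and is validated by
perfect-reconstruction and linearity tests. One-way ANOVA with Tukey HSD for
fibrosis sweeps delegates to `stats::aov`/`TukeyHSD` as a reporting
convenience.

## Synthetic data: what it does and does not emulate

`make_sheet_pcd`, `make_electrode_grid` and `make_recorded_egm_set` generate
desk-scale stand-ins for the clinical inputs: a curved sheet sampled at
1 mm, an electrode raster at a blood-pool standoff, and pseudo-recorded
EGMs with planar-wave LATs at a configurable CV, truncated-normal
amplitudes, Gaussian LAT jitter and optional fractionation. The waveform
template is a derivative-of-Gaussian biphasic (RS) deflection — the
canonical far-field→near-field unipolar shape — whose steepest downslope
sits exactly at the nominal LAT, so feature-extraction oracles are exact.
Fractionation inserts *single-lobe* bumps after the main complex so each
inserted bump adds exactly one countable deflection (time-shifted copies of
the full biphasic template would add two, breaking the construction
oracle). The clinical papers do not describe recorded-EGM noise statistics;
these distributions are stand-ins that give the pipeline the right
*structure* (LAT gradients, amplitude spread, deflection-count variation),
not estimates of any patient. Passing tests on these fixtures demonstrate
correctness of the machinery, not clinical fidelity of amplitudes or
morphologies.

## Numerical behaviour and problem sizes

Explicit monodomain CV converges slowly in element size because the
depolarization front is only ~0.5 mm wide: on a plane-wave strip we measure
17.5 → 32.1 → 42.2 → 46.2 → 48.0 cm/s at h = 1 → 0.5 → 0.25 → 0.125 →
0.0625 mm (dt-independent below 0.01 ms). This is why the construction
pipeline refines to 200–300 µm, and why the package's conduction-velocity
property tests run on 0.125 mm strips: there the √σ law holds within a few
percent and one further refinement changes CV by under 5%. Tests and
examples otherwise use 1 mm desk meshes (hundreds to thousands of
elements), where wave propagation, electrogram morphology and fibrosis
trends are qualitatively correct even though absolute CV is depressed —
the calibration stage exists precisely to absorb that bias. The fibrosis
trend study uses a 20 × 20 × 2.3 mm slab at 1 mm with ten noise seeds per
density; the end-to-end identity check and the demonstration pipeline use
the same slab.

## Known limitations

* Monodomain only; no bath-loading effect on propagation (the blood pool
  enters only through σ_b in the forward model).
* The infinite-medium forward model ignores boundaries and electrode
  surface averaging.
* The fiber rule is an analytic stand-in, not a histological atlas; mapping
  handles translation and scaling but not rotation, as in the atlas
  approach it mirrors.
* Fibrosis is purely non-conductive exclusion — no conduction slowing or
  ionic remodelling variants.
* Single-sheet geometries only: the projection-based reconstruction is for
  sheet-like regions like the LAPW, not closed chambers.
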