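---
title: "From CT-like volumes to simulation-ready airway geometry"
author: "airforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From CT-like volumes to simulation-ready airway geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airforge)
```

# The problem

Computational fluid and particle dynamics (CFPD) of the human respiratory
tract needs geometry of a quality that raw medical-image segmentations never
deliver: a closed, orientable, consistently wound triangle surface with
planar, labeled inlet and outlet faces, and physically meaningful boundary
conditions. Preparing one subject by hand — segmenting the airway, repairing
the marching-cubes surface, finding every distal opening, capping each one
flat, and writing the solver case — takes a working day or two. airforge
automates that chain and adds the utilities that turn particle-deposition
results into radioactive point-source batches for Monte Carlo dose
assessment.

Every stage is exercisable on synthetic data generated by the package
itself, so the complete pipeline is testable without any imaging data.

# The synthetic fixtures and what they do (and do not) emulate

`make_ct_phantom()` builds Hounsfield-unit volumes: soft tissue at 40 HU by
default (anywhere in the plausible 0–60 HU band), air cavities at −1000 HU,
optional metal inserts above 2000 HU, and additive Gaussian noise. The noise
default in the examples (10–20 HU) is the level at which a 3×3×3 median
filter is plainly useful without overwhelming the air/tissue contrast of
roughly 1000 HU. Cavities are analytic (tube segments, spherical pockets)
or voxelized tube trees, each with an exact ground-truth mask, and the
world frame is `world = index · spacing + origin` with z the through-plane
axis.

What phantoms do **not** emulate: partial-volume blur at air–tissue
interfaces, beam hardening, anatomy (turbinates, sinus ostia near the
scanner's resolution limit), and ambient air surrounding a head. Passing
the phantom suite therefore demonstrates the correctness of the chain's
logic and numerics, not clinical segmentation accuracy.

`make_tube_tree()` builds symmetric bifurcating trees: root radius 4 mm by
default with a per-generation decay of 0.8 — the scale of an adult trachea
down to proximal bronchi — and a 35° bifurcation half-angle, with branch
planes alternating 90° between generations so branches spread in 3D. The
mesh is the isosurface (marching tetrahedra) of the implicit union of
capsules around the skeleton. That construction guarantees a closed
2-manifold by construction, which is why it was chosen over sweeping and
welding polygonal cylinders at the junctions: welding sphere/cylinder
trimming is exactly the kind of code that produces the defects this package
exists to repair. The `resolution` parameter (effective circumferential
facet count) maps to the sampling pitch. An *open* tree has its root and
terminal end-caps cut away by local planes, exposing exactly `2^n + 1`
boundary loops for `n` generations — the outlet-count relation that the
capping stage must reproduce.

`inject_defects()` produces the four artifact classes that raw isosurfaces
exhibit — holes, non-manifold fins, inconsistent winding, near-duplicate
vertices — with a manifest, so repair can be tested against known ground
truth.

# Segmentation of the extrathoracic airway

The classical chain is: optional sinogram-space metal-artifact reduction;
3×3×3 median denoising; linear windowing of HU into [0, 1] with `I0 = −900`
(below is air) and `I1 = −115` (the fat threshold; above is tissue);
slice-wise Canny edge detection with morphological refinement (dilate, fill
holes, erode) and amplification of the masked voxels by cubing (darkening
the air side of edges); Laplacian enhancement `I − ∇²I` with the 6-neighbor
stencil scaled by voxel spacing; then marker-based 3D watershed and body
selection.

Design notes on points the algorithm family leaves open:

* **Canny dimensionality.** Canny is applied per axial slice and stacked;
  the classical detector is 2D and this matches the lineage of the
  approach. The hysteresis thresholds (0.1/0.2 of the peak gradient) and
  the Gaussian width (1.4 voxels) are exposed as arguments.
* **Watershed markers.** Air seeds are connected regions of strongly
  air-like voxels (enhanced value < 0.2); the background is seeded from
  air-like voxels on the in-plane (x/y) volume borders and discarded after
  flooding. The through-plane faces are deliberately *not* background: an
  airway exits a scan inferiorly, while ambient air surrounds the head
  in-plane. This consolidates the background-rejection pass into the 3D
  watershed rather than running separate 2D per-slice watersheds; on
  phantom geometry the result is identical.
* **Body selection.** The final mask keeps the largest interior body plus
  every isolated body whose volume lies in the oral-cavity window of
  (3, 9.66) cm³; other isolated bodies (mastoid-cell-like pockets,
  disconnected sinus fragments) are dropped. The older rule of discarding
  everything under 15 cm³ is deliberately not used — it would remove the
  oral cavity itself.
* **Metal-artifact reduction** is the textbook inpainting scheme: per
  slice, threshold the metal, forward-project (Radon by rotation and
  column sums), replace projection bins crossing metal by 1D linear
  interpolation along the detector axis, reconstruct with filtered
  backprojection, and restore the metal voxels. It removes streaks; it is
  not a clinical-grade MAR.

`extract_surface()` converts the mask to a triangle mesh in world
millimetres. By default the binary mask is first turned into a signed
distance field (inside minus outside distance transforms) with two light
diffusion passes, and the zero level set is extracted with marching
tetrahedra; this removes the staircase kinks a binary isosurface carries
(which otherwise inflate surface area by ~15 %) while a sign-preservation
step keeps voxel-scale features alive. Orientation is outward by
construction.

# Mesh repair

The repair loop is deliberately simple and set-theoretic:

1. merge near-duplicate vertices (tolerance `1e−6 cm = 1e−5 mm`, exposed);
2. remove every face containing an edge shared by more than two faces,
   then drop orphaned vertices;
3. extract the boundary graph of incidence-1 edges, walk it into closed
   cycles, and fill each: a 3-cycle is the missing triangle, a 4-cycle is
   split along one diagonal, larger holes are projected onto their
   best-fit (principal-component) plane and ear-clipped. New faces are
   wound so each shared edge is traversed oppositely to its neighbor.

The loop repeats until every edge has incidence exactly two, then a global
breadth-first winding pass enforces consistency and flips each closed shell
to positive signed volume. Vertex merging runs at the top of each iteration
(and again after filling): duplicate-vertex cracks otherwise present
degenerate "holes" to the filler. On the randomized defect suite the loop
converges in one or two iterations; three is the observed ceiling, matching
the behavior expected of this procedure on real airway meshes. Ear clipping
replaces a constrained Delaunay triangulation (no installed R library
provides one); both add exactly `|h| − 2` triangles to a simple hole of
size `|h|`, and a fan fallback covers projections that self-intersect.

Smoothing is Taubin's two-pass filter with uniform (combinatorial)
Laplacian weights: a shrink step of weight λ = 0.60 followed by a dilation
step of weight −ν = −0.635, repeated n = 20 times, under the stability
requirement `0 < 1/λ − 1/ν < 0.1` (the defaults sit at 0.0919; violating
parameters are rejected). Uniform weights were chosen over cotangent
weights because the input meshes are near-uniform isosurface triangulations
where the two coincide in practice, and uniform weights cannot produce the
negative cotangent pathologies of low-quality input. The companion
`laplacian_smooth()` exists mainly as the comparison baseline: on a
subdivided icosphere 20 Taubin iterations change the enclosed volume by
well under 2 % while the λ-only filter loses more than 5 %.

Quality is reported as the per-face shape factor `SQ = 4√3·A / Σ lᵢ²`
(1 for equilateral, 0 for degenerate) and the minimum internal angle.

# Centerlines

The medial-axis machinery is the distance-transform realization of the
maximal-inscribed-sphere picture: the interior of the (closed) mesh is
voxelized by ray-parity, and the Euclidean distance transform of the
interior gives each voxel the radius of the largest ball centered there.
An exact polygonal Voronoi medial axis would be noise-prone at this mesh
quality and is not attempted.

The front propagation solves `|∇T| = 1/r(x)` — speed equal to the local
inscribed radius, so the arrival time accumulates the path cost `∫ ds/r`
and wide lumens are fast. (The prose convention "speed is the inverse of
the radius" contradicts that equation; the equation is authoritative, since
only it makes centerlines prefer the lumen center.) The solver is a
second-order upwind fast-marching method with exact initialization in a
small ball around the source; both refinements are needed to stay within a
few percent of an independent Dijkstra oracle on a 5×5×5-neighborhood
voxel graph.

Endpoints are seeded automatically: local maxima of the unit-speed
(geodesic) arrival field from the widest interior voxel are re-centred onto
the medial ridge (largest-radius voxel within an arrival-time band of about
one lumen radius), walked tipward along the ridge while the inscribed
radius stays above 70 % of the lumen, and deduplicated by a radius-scaled
suppression distance. This replaces template-based 3D thinning (no
installed implementation, and hand-rolled thinning tables are a large
correctness risk); on tubular geometry both definitions land on the same
degree-1 terminals. Because the stopping rule is tied to the lumen radius,
not the grid, endpoint positions move by less than about two voxels when
the pitch is halved; sub-voxel agreement is not attainable, since the ridge
walk necessarily quantizes at one voxel.

The inlet is the endpoint with the largest inscribed radius (ties within
2 % broken by the mean radius in a 2-pitch ball, then by index). Paths are
traced from every other endpoint by steepest descent on the arrival field
(trilinear interpolation, half-pitch steps, plateau escape to the lowest
neighbor), merged on shared prefixes into a branch graph, and resampled at
0.5 mm arc length (configurable; 0.5 mm resolves the smallest airway
branches this pipeline targets).

# Capping

Each endpoint is capped by the oriented-prism construction: a hexagonal
prism (12 vertices — the cheap stand-in for a thin cylinder) of circumradius
1.5× the local inscribed radius and thickness 0.3 mm (inside the workable
0.1–0.5 mm band: thick enough to separate the bodies, thin enough to lose
no anatomy), aligned to the outward centerline tangent
`n_b = (p_b − p_next)/‖·‖` by the Rodrigues rotation taking ẑ to `n_b`
(singular antiparallel case: rotation by π about x̂).

The boolean difference with the prism is realized as a *localized plane
cut*: the connected patch of faces beyond the cap plane and within the
prism's lateral extent is removed, straddling faces are split exactly on
the plane, and the resulting planar loop is fan-triangulated around its
centroid as the cap patch. For a prism that fully transects the lumen this
is the same result a general mesh boolean would produce, with none of a
boolean backend's failure modes. The cut plane is placed adaptively: just
inside an open rim (detected endpoints sit up to a lumen radius short of
their opening), just inside an already-flat closed end, or a bounded depth
into a rounded dome so the cap still spans a nearly full cross-section;
for mid-lumen transection requests it sits half a thickness inside the
requested point, so re-capping an already capped end trims less than one
thickness. After all endpoints are capped the largest connected body by
enclosed volume is retained, patch areas and centroids are computed, and
the largest-area cap becomes the inlet — on an airway the trachea (or
nostril) always dominates the distal outlets.

# Boundary conditions and particle physics

The flow side collects the printed settings of the reference configuration:
sinusoidal breathing `Q(t) = Q_max · sin(2πt/T)` with `Q_max = 100 L/min`
and `T = 2 s` (heavy breathing; the cycle mean of |Q| is `2Q_max/π ≈ 63.7
L/min`), inlet speed `‖u‖ = Q/A`, isotropic-turbulence inlet values
`k = (3/2)I²u_ref²` at `I = 4 %`, `ω = √k/(C_μ^{0.25} L)` with `C_μ = 0.09`
and `L` the inlet hydraulic diameter, intermittency `γ = 1`, and the
transition momentum-thickness Reynolds correlation

`Re_θ = 1173.51 − 589.428·Tu + 0.2196/Tu²` for `Tu ≤ 1.3`, else
`331.5·(Tu − 0.5658)^{−0.671}`,

with `Tu = 100·√(2k/3)/u_ref` (identically `100·I` at the inlet). The
`0.2196/Tu²` and negative-exponent readings make the two branches continuous
at `Tu = 1.3` (gap ≈ 0.1 %); the typeset forms without the division are
discontinuous by an order of magnitude and cannot be what the model means.
`Tu` is floored at 0.027, the conventional guard for the `1/Tu²` term.

Particle helpers implement slip-corrected Stokes drag
(`C_c = 1 + Kn(1.257 + 0.4·e^{−1.1/Kn})`, `Kn = 2λ/d`, the classical
constant set — the correlation's constants are configurable) and the
Brownian force `F = ξ·√(2 k_B T₀/(α Δt))` per component with mobility
`α = 1/(3πηd)` from the Einstein relation; `ξ` is standard normal. Lift
and virtual-mass forces appear in the transport equation but carry no
specified model here and are intentionally not implemented. `emit_case()`
wraps everything — per-patch boundary types (no-slip walls, waveform inlet,
fixed-pressure outlets), at least 100,000 particles with stick-on-contact
walls, and the non-default hexahedral meshing parameters as pass-through
text — into a JSON case, optionally rendering OpenFOAM-style field
dictionaries.

# Dose preparation

Deposition records (position, diameter, stuck/escaped) are converted to
point sources with activity `A = V·a·ρ` (specific activity in Bq/kg,
density in kg/m³). The Monte Carlo transport limit of 500 point sources
per simulation drives batching; with dual decay (coupled γ + β sources per
particle) only 250 particles fit per batch, so the reference case of 1154
deposited particles yields five batches. The ICRP correction for
deposition in unresolved distal airways enters `nDF = (nStick +
nScape·ICRP)/nTotal` as an input scalar or per-diameter table — it comes
from external dosimetry tooling and is deliberately not computed here.
Alignment to a reference phantom frame is rigid: translate the tracheal
carina onto the reference carina, rotate the tracheal axis onto the
reference axis (Rodrigues), preserving all pairwise distances to 1e−9.
Whether the γ and β sources split or duplicate the particle activity is
not derivable from the reference description; both sources carry the full
particle activity here and the emission probabilities are left to the
transport code.

# Numerical choices and problem sizes

* Vertex-merge tolerance 1e−5 mm; cap planarity comes out at machine
  precision because cut vertices are constructed on the plane.
* Marching tetrahedra (uniform Kuhn decomposition, welded lattice-edge
  vertices) rather than classic marching cubes: the tetrahedral cases are
  unambiguous, so closed inputs give watertight, manifold output without a
  256-entry case table; triangle orientation is fixed per tetrahedron by
  the local field gradient.
* Voxelization parity rays carry a ~1e−4-voxel deterministic jitter so
  lattice-aligned synthetic meshes avoid exact edge hits.
* The test and acceptance workloads use grids of 32³–80³ voxels, icospheres
  of 320–5120 faces, and trees up to four generations at reduced
  circumferential resolution — sizes at which every stage's behavior is
  already asymptotic but a full run stays in minutes on one core.
* Smoothing comparisons use a subdivision-4 icosphere: volume fidelity
  under Taubin is resolution-dependent, and at 5120 faces the
  discretization's own shrinkage is negligible against the 2 % criterion.

# Known limitations

* The watershed background rule assumes airways exit through-plane; a scan
  cropped so the airway exits laterally would need the border-marker axes
  changed.
* Endpoint seeding is built for tubular geometry; blob-like cavities with
  no tips (a sphere) correctly fail with "fewer than 2 endpoints".
* The localized plane cut assumes the cap prism transects a single lumen;
  openings closer together than the cap diameter would need true booleans.
* Self-intersecting faces are detected only insofar as they create
  non-manifold edges; geometric (edge-crossing) self-intersection is not
  resolved.
* The OpenFOAM dictionary rendering is a text convenience, not a complete
  case directory.
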