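---
title: "vessim: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vessim: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vessim implements the computational core of a percutaneous coronary
intervention (PCI) training simulator: extracting curve skeletons
(centerlines) from vessel surface meshes, simulating a guidewire or catheter
as a chain of rigid rods that minimises a potential energy against the
vessel wall, and rendering fluoroscopy-like images by X-ray attenuation.
Everything is exercised on synthetic vascular phantoms with analytic ground
truth, so no clinical data is needed to validate the pipeline. This vignette
documents the models, the tunable parameters, and the numerical choices a
maintainer would want to know about.

## Centerline extraction

### Laplacian contraction

`contractMesh()` shrinks a watertight triangle mesh toward its skeleton by
iteratively solving, per coordinate, the stacked least-squares system

$$\begin{bmatrix} W_L L \\ W_H \end{bmatrix} V' =
  \begin{bmatrix} 0 \\ W_H V \end{bmatrix},$$

where $L$ is the cotangent Laplacian of the current mesh, the scalar $W_L$
weights the smoothing/shrinkage block and the diagonal $W_H$ anchors
vertices to their previous positions. After each solve $W_L \leftarrow s_L
W_L$ (default $s_L = 2$) and $W_{H,i} \leftarrow W_{H,i}^0
\sqrt{A_i^0/A_i^t}$, where $A_i^t$ is the current one-ring area; the
Laplacian is rebuilt from the new positions. The loop stops when the mesh
volume falls below $10^{-5}$ of the input volume ("nearly zero"), or after
`maxIters = 20` iterations.

Two numerical choices deserve explanation:

* **Initial contraction weight.** We start at $W_L^0 = \sqrt{\bar A}$
  ($\bar A$ = mean face area). The frequently quoted $10^{-3}\sqrt{\bar A}$
  start leaves the first ~10 iterations as numerical no-ops on tube meshes:
  the displacement is a bilaplacian perturbation whose volume change can
  even be slightly positive, and the iteration budget is wasted before
  contraction begins. At $\sqrt{\bar A}$ the volume decreases strictly from
  the first iteration at identical final accuracy (0.105 vs 0.104 mm axis
  error on the reference cylinder).
* **Degeneracy safeguard.** Once a mesh has collapsed to a quasi-1D shape
  its volume is dominated by folding noise; forcing further volume reduction
  makes the collapsed *curve* contract, which drags bent vessels toward
  their chord (on the 90° bend phantom the error grows from 0.36 mm to
  4.2 mm in two extra iterations). An iteration that fails to reduce the
  volume while the collapse is already past half the original volume is
  therefore discarded and contraction stops.

Cotangents are clamped to $|\cot| \le \cot 1^\circ$ so sliver triangles do
not destroy the conditioning of the solve; an ill-conditioned solve is
retried once with a $5^\circ$ clamp.

### Adaptive subdivision, classification and clustering

`adaptiveSubdivide()` splits faces with any edge above a target length
(Loop edge mask on interior edges, midpoints on boundaries; conforming
1-to-2/1-to-3 splits on neighbours), increasing the point density of the
contracted mesh before the skeleton is extracted *on the point domain*.

`classifyPoints()` computes, per point, the largest-eigenvalue fraction
$f = \lambda_1 / (\lambda_1 + \lambda_2 + \lambda_3)$ of the covariance of
its neighbourhood. $f \to 1$ on line-like runs (branch points), $\to 1/2$
on planar membranes, $\to 1/3$ in isotropic blobs; a point is a *joint
point* iff $f < \psi_f$, with $\psi_f = 0.8$ by default (deliberately
generous so no junction is missed). Ties ($f = \psi_f$ exactly) are branch
points.

The neighbourhood is radius-based, because subdivision makes the density
non-uniform. The radius default is the **mean distance from contracted
vertices to the original surface — i.e. the local lumen radius**. This is
the physically meaningful scale: a contracted junction collapses to a
membrane whose extent is set by the vessel calibre, not by the mesh
resolution. Mesh-relative radii (a small multiple of the mean contracted
edge length) fragment one junction membrane into several clusters.

`clusterJoints()` floods joint points through the same spatial radius with
a BFS queue; clusters partition the joint points and their arithmetic means
become junction candidates.

### Skeleton growing

`growSkeleton()` grows branch polylines from seeds. For each joint cluster,
branch points in a shell just outside the cluster are grouped into
connected components — one per incident branch — and the member of each
component nearest the cluster center becomes a seed. A front then steps
repeatedly to the centroid of the unvisited branch points inside a forward
cone (half-angle 60°, reach twice the step length, step = 0.75 of the
classification radius); it stops when nothing is left ahead or merges when
it comes within one step of another front. Unbranched vessels grow from
their two extremal points toward each other.

Robustness choices, each visible in the code:

* a front that would advance by less than 0.3 step consumes the thin shell
  ahead without creating a node (noise suppression), and the growing
  direction is the average of the previous direction and the last
  displacement;
* everything within (cluster radius + one step) of a cluster center is
  excluded from growth: the collapsed membrane has a line-like *rim* that
  classifies as branch points, and fronts that trace the rim produce
  spurious near-junction detours;
* the junction node is placed at the least-squares intersection of the
  lines carried by the first few grown nodes of each incident front. The
  cluster center (the membrane centroid) is a biased junction estimator
  whenever the membrane is asymmetric; the line intersection recovers the
  point where the branch axes actually meet, with the center as fallback
  when fewer than two incident lines exist or the solution drifts more
  than six steps away.

Each branch is finally fitted with a clamped cubic B-spline
(`fitBSpline()`, chord-length parameterisation, exact endpoint
interpolation, interpolating by default; `smoothing > 0` reduces the
control-point count for noisy inputs, and branches with fewer than four
nodes fall back to quadratic/linear). Per-node lumen radii are estimated as
the distance to the nearest original-surface vertex. `labelBranches()`
transfers branch identities back to the surface by nearest skeleton node,
and `sampleCameraPath()` yields arc-length-uniform endoscopic camera poses
with spline-derivative tangents.

On the reference phantoms (2 mm lumen), extracted nodes track the analytic
centerlines to ~0.1–0.35 mm along tube runs. Two regions are harder:
junction fillets (the contracted shape genuinely cuts the corner between
merging tubes) and the spherical end caps of capsule phantoms, where a few
nodes can deviate up to ~1 mm. This is an intrinsic feature of
contraction-based skeletons, not a tuning artifact.

## Guidewire mechanics

The instrument is a chain of rigid rods joined at points $x_i$, with an
intrinsic bias angle $\varphi_i$ and a bending stiffness $C_i$ per interior
joint. Rods bend but never stretch; after every operation each rod length
equals its rest length to machine precision (constraint-projection sweeps
plus an exact forward pass).

The total potential energy is $E_\mathrm{total} = E_g + E_v$ with

$$E_g = \sum_i \tfrac12 C_i (\theta_i - \varphi_i)^2, \qquad
  E_v = \sum_i \tfrac12 k_v d_i^2,$$

where $\theta_i$ is the inter-rod angle, $d_i$ the wall penetration depth
and $k_v$ the wall's elastic coefficient. The angle $\theta$ is the pure
inter-rod angle (no torsional component — the energy is bending-only), and
$C_i$ is a free per-joint parameter rather than being derived from a
Young's modulus.

### Equilibrium with one collision detection

`stepEquilibrium()` performs a single collision detection
(`detectCollisions()`: radial penetration against the analytic lumen, with
inward unit normals; joints beyond an open end are flagged escaped), seeds
the wall forces $F_i = k_v d_i n_i$, and then minimises the energy under
the rod constraints by projected gradient descent with Barzilai–Borwein
spectral steps and backtracking (plain gradient steps crawl on the chain's
soft sliding modes). During the inner loop the wall geometry stays frozen:
the wall term uses depths linearized along the contact normals, and the
applied force follows the correction law

$$F_i' = F_i \left(1 - \eta \frac{\alpha_i \cdot F_i}{\|F_i\|^2}\right),$$

with $\alpha_i$ the joint's displacement over the previous inner iteration.
The scale factor is clamped below at zero so a contact force never
reverses. With $\eta = k_v$ the correction reproduces the linearized depth
update exactly, which motivates the defaults $\eta = 0.5\,\mathrm{mm}^{-1}$
and $k_v = 0.5$; movement *against* the force deepens it, as physics
demands. The monitored energy trace is non-increasing by construction
(backtracking); the loop stops when the largest joint displacement falls
below `tol` (default $10^{-4}$ mm) or after `maxInner = 200` iterations.

With $\eta = 0$ the forces keep their single-detection values — the
uncorrected scheme of earlier simulators. That scheme is not merely slower:
a constant force on a base-clamped chain has no opposing wall in the frozen
model, so its equilibrium sits a cantilever deflection ($\sim P L^3 / 3C l$)
away. The package reports both iteration counts; the corrected loop
converges, the uncorrected one does not reach the same state. The
comparison test documents this asymmetry rather than hiding it.

### Maneuvers and events

`pushPull()` transports the wire along its own spatial path (extended
straight past the tip), creates or removes entry-side rods so the base
stays at the entry with rods near the nominal length, updates the inserted
length exactly, and re-equilibrates with a configurable number of outer
steps (each with its own collision detection — this is the per-frame loop
of a simulator). `twistChain()` realizes twist kinematically: the chain has
no torsion energy, so rolling the handle rotates the intrinsic-bias plane
of the tip about the local tangent; all inter-rod angles, and hence the
energy, are invariant. `checkRupture()` fires a rupture event iff the tip
wall-force magnitude *strictly exceeds* the vessel's boundary force.

`computeNd()` implements the adaptive discretization law: the target rod
length is the chord subtending the maximum bias angle $\varphi_m$ at the
outer-lumen radius, $L^* = \sqrt{(r_c + d_v/2)^2 \cdot 2(1-\cos\varphi_m)}$,
and $n_d = \mathrm{round}(\log_2(\bar l_t / L^*))$: positive $n_d$ splits
each rod into $2^{n_d}$, negative merges groups of $2^{-n_d}$
(`rediscretize()`, lossless for splits, chord-vs-arc discrepancy reported
for merges). Instrument geometry is validated against accepted clinical
ranges (guidewires 0.254–0.965 mm, catheters 1.33–2 mm diameter, lengths
60–260 cm); out-of-range values warn but do not block.

## X-ray rendering

`renderXray()` computes, per pixel, the linear thickness $u_j$ of every
object and applies the Beer–Lambert law $I = e^{-\sum_j \sigma_j u_j}$:
attenuations of overlapping objects multiply. Thickness is computed on the
CPU — for meshes by rasterizing each triangle in image space (a half-open
edge rule prevents double counting on shared edges) and accumulating
$\mathrm{sign}(d \cdot n)\, t$, which telescopes to the entry/exit
thickness of a closed mesh; for rod chains analytically, as chord lengths
through the union of rod capsules at the instrument radius (adjacent
capsules overlap at the joints; the overlap is one rod-radius sphere and is
counted once per rod, a deliberate simplification). The default camera is
orthographic (parallel-beam fluoroscopy approximation); a pinhole camera
provides C-arm-like perspective. Default attenuation coefficients
(contrast-filled vessel 0.05/mm, guidewire 1.0/mm) are visually plausible
placeholders and fully configurable. `rayThickness()` is the single-ray
primitive, with best-effort pairing and a warning on unbalanced
intersection sequences (open meshes).

## Synthetic phantoms

`makePhantom()` builds watertight lumen meshes together with the analytic
ground truth (centerlines, radii, junction positions, an inside/outside
predicate) and a matching collision model:

* **cylinder** and **torus_segment** are swept tubes (configurable
  circumferential × axial resolution, default 32 × 80) with flat end caps;
  optional Gaussian surface jitter (default off, so oracles are exact)
  emulates segmentation noise; identical spec + seed is bit-identical.
* **y_bifurcation** and **composite** networks are meshed by marching
  tetrahedra (Kuhn 6-tet decomposition) over the capsule-union signed
  distance field, which guarantees watertightness across junction blends.
  The grid uses the half-offset lattice (symmetric about the coordinate
  planes, never exactly tangent to round-coordinate surfaces), faces are
  wound consistently by BFS propagation, and the mesh receives two light
  uniform-Laplacian smoothing rounds — marching-tetrahedra slivers
  otherwise leave straggler vertices behind during contraction. Free tube
  ends carry spherical caps; the ground-truth centerlines extend into the
  caps, and daughter-branch collision models taper their lumen radius
  spherically there.

The default Y geometry (2 mm lumen, 20 mm trunk, 15 mm daughters at ±30°
off the trunk axis) is a generic epicardial bifurcation at roughly CT
segmentation scale. What the phantoms do *not* emulate: tapering lumens,
eccentric lesions, vessel-wall compliance (the wall is rigid, as in a
silicone bench phantom), motion, and image noise — so green tests here
demonstrate correctness of the geometry/physics/rendering pipeline, not
clinical robustness.

## Problem sizes and budgets

The test-suite and the acceptance script run the swept phantoms at 32 × 80
(≈2.6k vertices), the branched phantoms at a 0.4 mm grid (≈18k vertices),
guidewires with 8–20 rods of 2 mm, and renderings at up to 256². These
sizes keep a full run in a few minutes on one CPU while leaving every
accuracy margin intact; all of them are plain function arguments.

## Known limitations

* Junction fillets and capsule cap tips can push a few skeleton nodes to
  ~1 mm from the generating centerline (see above); downstream consumers
  needing sharper corners should refit splines with the junction pinned.
* The guidewire model has no torsion energy, no friction, and no
  blood-flow interaction; coaxial guidewire-in-catheter mechanics are not
  modelled (each instrument is an independent chain).
* The constant-force (η = 0) baseline does not converge to the corrected
  equilibrium — an intrinsic property of the uncorrected scheme, reported
  as such.
* The renderer has no scatter, beam hardening, or detector noise model;
  loop-containing vasculature (non-tree topology) is out of scope for the
  skeletonizer.
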