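---
title: "Methods: reduced shell-FE contact modelling of mask fit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reduced shell-FE contact modelling of mask fit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maskfit)
```

`maskfit` estimates the contact pressure a rigid facial mask exerts on a soft
face, fast enough to screen hundreds of design variants. This vignette is the
package's own account of the model, its assumptions, the numerical choices
behind each stage, and what the tests do and do not demonstrate.

## The mechanical model and its assumptions

The analysis is **linear elastic and static**. Five modelling assumptions
make that defensible for design screening: (1) face and mask form a two-body
contact; (2) the contact area is treated as fixed within a solve; (3) no
detachment, sliding or friction is modelled; (4) contact acts only along the
push axis of the mask (the Z axis by convention); (5) the mask is far stiffer
than skin and is treated as perfectly rigid, so only the face deforms. Under
these assumptions a mask "worn" by pushing it a few millimetres onto the face
produces a pressure field that ranks designs; it does not predict the exact
pressures of a strapped, breathing, moving wearer.

### Face: single-layer flat shell

The face surface (a triangulated scan, or the synthetic generator below) is
modelled as one layer of triangular flat-shell elements rather than a layered
solid of skin/fat/bone. This trades absolute accuracy for two decisive
properties: the model is built directly from the surface mesh with no
volumetric meshing, and the stiffness assembly takes seconds.

Each element superposes three blocks with the plane-stress pattern
$M = \begin{bmatrix}1&\nu&0\\\nu&1&0\\0&0&(1-\nu)/2\end{bmatrix}$:

* membrane (constant-strain triangle), rigidity $D_p = \frac{E}{1-\nu^2}M$
  integrated over the thickness $h$;
* plate bending (Mindlin), rigidity $D_b = \frac{Eh^3}{12(1-\nu^2)}M$;
* transverse shear, rigidity $D_s = \kappa G h$, $G = E/2(1+\nu)$,
  $\kappa = 5/6$.

**Shear interpolation.** The naive linear Mindlin triangle locks in the thin
limit even with one-point shear integration: on the clamped-plate benchmark
below it was still 26% too stiff at a 32×32 mesh. The package therefore
computes the shear strain from *discrete shear gaps*: the gap of node $i$
relative to node 1 is $w_i - w_1$ plus the edge integral of the linearly
interpolated section rotations, and differentiating the linearly interpolated
gap field gives a constant element shear strain. This keeps the bending,
membrane and shear blocks separate (the constitutive matrices above enter
unchanged) while eliminating the spurious thin-limit constraints; the same
benchmark error falls to 0.2%.

**Six global DOFs per node.** The local element has 15 DOFs (3 translations
and 2 rotations per node — the in-plane "drilling" rotation carries no
stiffness in a flat shell). Globally each node is given all 6 DOFs and the
drilling rotation receives an artificial stiffness of
`drilling_factor` (default $10^{-6}$) times the largest bending diagonal,
which prevents singular assemblies on near-coplanar patches without
measurably polluting the response. A 5,303-node mesh therefore carries
31,818 DOFs.

**Boundary condition.** Every vertex on an open edge (an edge used by exactly
one triangle) is clamped in all 6 DOFs. This is the whole scan rim; it
represents the face continuing into the head, and it makes the free stiffness
block positive definite.

### Material parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `E` | 0.03 | MPa | soft-tissue elastic modulus for facial skin |
| `nu` | 0.49 | — | near-incompressible soft tissue; 0.5 exactly is singular and rejected |
| `h` | 2 | mm | effective single-layer shell thickness |
| `kappa` | 5/6 | — | standard Mindlin shear correction for homogeneous sections |
| `drilling_factor` | 1e-6 | — | drilling stabilization scale; 0 is allowed for flat benchmark meshes |

Units are consistent mm / MPa / N (MPa·mm² = N) everywhere, including files.

### Mask: periodic spline through reference points

The mask's contact surface is reduced to the geometry that matters for
contact: a closed **reference line** through $n \ge 4$ designer-chosen 3D
points, interpolated per coordinate by a periodic cubic spline. The knot
curvatures solve the cyclic tridiagonal continuity system
$l_{k-1} g''_{k-1} + 2(l_{k-1}+l_k) g''_k + l_k g''_{k+1} = 6(\Delta_k - \Delta_{k-1})$
with value/tangent/curvature matched at the seam. The parameter is cumulative
chord length (shape-preserving for unevenly spaced points; the
parameterization is otherwise free). The production solver is O(n) — Thomas
elimination plus a Sherman–Morrison correction for the cyclic corners — and
is tested against a dense solve of the same system.

Contact nodes are sampled at equal arc-length intervals (`spacing`, default
1.0 mm, matching typical contact-node density; the section count is
`round(L/spacing)` with a floor of 8). Arc length is accumulated by composite
Simpson quadrature on a dense parameter table (100 subintervals per piece,
errors far below the 1e-6 relative target) and inverted by monotone
interpolation of that table. Cross-section frames use the
**double-reflection rotation-minimizing frame** rather than Frenet, which is
undefined at inflections and flips at curvature sign changes; consecutive
frames rotate by only a few degrees at 1 mm spacing. The cross-section
profile itself is configurable — the default is a single point (a contact
line), with an optional flat strip of m points — because the contact model
consumes only the sampled nodes; nothing downstream depends on the profile
shape.

One subtlety: for *collinear* reference points the closed loop must run out
and back along the line, so each coordinate's data is a tent function of the
parameter and the 1-D curvatures cannot vanish. The meaningful property —
the evaluated curve stays exactly on the line, by linearity of the spline
operator — holds to 1e-9 and is what the tests assert.

## Static condensation

The face only ever touches the mask near the contact loop. For a family of
design candidates, the **master nodes** are the union, over all candidates,
of the three vertices of the face triangle nearest each mask node (exact
point-to-triangle distances with a vertex-proximity prefilter), minus clamped
boundary vertices. All 6 DOFs of each master node are retained — contact uses
only the push-axis translation, but keeping whole nodes leaves the axis
choice to the contact stage. The free DOFs are partitioned into master and
slave and the reduced stiffness is the Schur complement
$K_r = K_m - K_c^{\mathsf T} K_s^{-1} K_c$, computed with one sparse Cholesky
factorization of the slave block and multi-RHS solves (the inverse is never
formed); $K_r$ is stored dense, since it is small and dense by nature. For
statics this reduction is **exact**: for any load supported on master DOFs,
the reduced solve plus the recovery
$u_s = -K_s^{-1} K_c u_m$ reproduces the full solve — the test suite verifies
agreement to 1e-8 relative on synthetic faces of 200 and 2,000 nodes, and the
recovery factorization is reused across all candidates of a sweep.

## Contact solve

Each mask node is paired with its nearest master vertex (node-to-node;
constraints attach to DOFs, so nearest-vertex, not nearest-surface-point);
when several mask nodes map to one vertex the closest wins. With the mask
pushed `push_depth` (default 3 mm) along the approach axis, a pair's
prescribed penetration is `d_f = push_depth - clearance`. Pairs with
`d_f <= 0` never close and are dropped up front — these are the
zero-pressure patches of a badly fitting design. The remaining constraints
enter a saddle-point system in the reduced displacements and the Lagrange
multipliers $\Lambda$ (the nodal contact forces), solved by block
elimination: $S = C^{\mathsf T} K_r^{-1} C$,
$\Lambda = S^{-1}(C^{\mathsf T} K_r^{-1} f_r + d_f)$, with signs fixed so
compressive forces are positive. An **active-set loop** then removes pairs
whose multiplier comes out tensile and re-solves until all retained
$\Lambda \ge 0$ (cap 50 iterations; 2–5 are typical). The mask being rigid,
its stiffness never enters; the mask-side reaction is reported as
$-\sum\Lambda$. External forces `f_r` default to zero — the only loading is
the prescribed mask displacement entering through `d_f`.

Built-in invariants, all tested: constraint residuals at machine precision
(well under the 1e-8 mm tolerance), complementarity (released pairs would be
tensile if re-added), monotonicity of total force in push depth, and global
equilibrium — the total contact force equals the reaction transmitted to the
clamped boundary along the push axis to 1e-6 relative.

## Nodal pressure and design ranking

The tributary area of a vertex is one third of the summed areas of its
incident triangles, so tributary areas partition the total surface area
exactly; nodal pressure is $\lambda/A$. Zero-pressure paired nodes are
included in the headline mean/SD/max — uncontacted patches are part of fit
quality — and the zeros-excluded variants are also exported, since either
convention is defensible. The SD is the population formula (divisor N).

Sweeps enumerate the full Cartesian offset grid (lexicographic order, first
adjustable point most significant) and rank candidates by the **sum of
z-standardized mean and z-standardized SD** of pressure: the fit criterion —
low average pressure and low spread — is inherently qualitative, and
equal-weight z-scoring turns it into a score that is symmetric, scale-free
(invariant under affine rescaling of all pressures), and configurable via
weights. Ties break by lower mean, then
enumeration order. A statistic that is constant across candidates
contributes 0 rather than NaN.

## The synthetic face generator

Real scan data cannot be redistributed, so the package generates
template-like stand-ins: a structured UV grid over a parametric height field
— a cosine dome (depth 70 mm over a 140×180 mm aperture) plus a Gaussian
nose ridge (default 22 mm high, 32 mm wide), a nasal-root depression and a
chin bump (12 mm) — triangulated with +Z-facing winding. Grid resolution is
chosen to hit the target vertex count within 2%; a small seeded jitter
(≤15% of a cell tangentially, ≤0.08 mm normally, interior vertices only)
breaks the perfect regularity of the grid the way template registration
never produces perfectly regular meshes, and makes generation bit-identical
per seed. Landmarks (sellion, pronasale, promentale, cheeks) are placed at
extrema of the generating function and stored as vertex indices so they
survive mesh operations. `mask_reference_points()` derives an 8-point
medical-mask loop (or a 12-point variant with extra points at the nasal-root
and lip sides) from the landmarks, floating `clearance = 0.5` mm off the
skin — the standoff of a mask resting on a face before it is pressed on.

What the generator does **not** emulate: real facial asymmetry, scan noise
and registration artefacts, regionally varying tissue thickness and
stiffness, and concave regions (eye sockets, nasolabial folds) sharper than
the smooth height field. Passing tests therefore demonstrate the
correctness of the *machinery* — element formulation, reduction exactness,
contact complementarity, conservation identities, which are
geometry-independent — and the *qualitative* design behaviour (adding
reference points at high-curvature regions does not increase the
zero-pressure count), not the absolute pressures of any real face. On the
synthetic dome with the default constants and a 3 mm push, mean pressures
come out around 2×10⁻⁴ MPa and maxima around 2×10⁻³ MPa; absolute levels
depend strongly on the surface geometry.

## Numerical choices and degenerate inputs

* Triangle local frames: e₁ along the first edge, e₃ the normal,
  e₂ = e₃×e₁ — deterministic and orientation-stable.
* Degenerate triangles (area ≤ 1e-9 mm²), repeated indices and non-finite
  coordinates are rejected at mesh construction with the offending element
  named; duplicate consecutive reference points are rejected at design
  construction.
* STL input carries no shared topology; vertices are merged by exact
  coordinate hash after snapping to a 1e-6 mm grid.
* The slave-block factorization failing (no clamped boundary) and a singular
  contact Schur complement (duplicate constraints) raise targeted errors
  rather than returning garbage.
* Sweeps precompute the dense inverse of $K_r$ once; per-candidate solves
  then reduce to submatrix extraction plus a small dense solve, which is why
  a candidate evaluates in ~0.1 s at the 2,000-node scale.

## Problem sizes used by the test suite

The suite verifies exactness properties at 200–2,000-node faces, runs the
plate benchmark at 8/16/32 grid refinements, checks DOF bookkeeping on a
5,303-vertex mesh, and runs a 3⁴ = 81-candidate sweep on a 2,000-node face
with a shared reduction — sizes chosen so the full suite completes in about
a minute while exercising every code path at non-trivial scale. The
acceptance script reruns the same pipeline end to end and reports the
computed quantities as JSON.

## Known limitations

* Linear kinematics: a 3 mm push on very soft tissue is at the edge of the
  small-strain regime; real tissue stiffens under compression.
* Homogeneous material: bone-backed regions (nasal bridge) are as soft as
  cheeks, which overestimates their compliance.
* No friction or tangential constraint; pressures are purely normal.
* Node-to-node pairing ties resolution of the pressure field to the face
  mesh density under the contact line.
* The rigid-mask assumption fails for thin flexible masks; two-flexible-body
  contact needs a different formulation.
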