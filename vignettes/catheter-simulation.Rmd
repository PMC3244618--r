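---
title: "Quasi-static catheter simulation by total potential energy minimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-static catheter simulation by total potential energy minimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cathfem)
```

## The model

During vascular interventional procedures a catheter or guidewire is a long,
very flexible rod confined inside blood vessels and manipulated only from its
tail. Between inputs it is observed to settle into a static shape, which
makes a quasi-static description natural: every push or pull maps the system
from one minimum of the total potential energy to the next, with no inertial
dynamics. `cathfem` implements that description. The total potential of a
catheter configuration is

$$\Pi \;=\; U_e \;+\; U_p \;-\; W,$$

with three terms:

* **Bending energy** $U_e$ of a Kirchhoff rod. Catheters hold torque well, so
  twist is neglected and only curvature is penalized:
  $U_e = \int_0^L \alpha\,\lVert \mathbf{t}'(s)\rVert^2\, ds$, where
  $\mathbf{t}(s) = \mathbf{x}'(s)$ is the unit tangent of the centerline and
  $\alpha$ the bending constant. Writing the energy in the tangent rather
  than the position avoids second derivatives.
* **Wall penalty** $U_p$. The vessel wall is a triangle mesh; each triangle's
  plane is stored as $g(\mathbf{x}) = \mathbf{n}\cdot\mathbf{x} + d$ with the
  unit normal oriented toward the lumen. When a catheter node penetrates a
  triangle, the wall deformation is modeled by Hooke's law on the penetration
  depth: $U_p = \sum_j \tfrac12 \kappa\, g(\mathbf{x}_j)^2$ over active
  contacts $j$, with $\kappa$ the wall's elastic modulus.
* **External work** $W = \sum_i \mathbf{f}_i \cdot
  (\mathbf{x}_i - \mathbf{x}_{i0})$, the work done by user-applied nodal
  forces over the displacement from the previous equilibrium. Friction is
  omitted: clinical catheters are coated to make it negligible. Minimizing
  $U_e + U_p - W$ is the standard stationary-total-potential convention —
  the equilibrium moves *with* an applied force. (A configuration flag
  `sign_convention = "paper_literal"` instead adds $+W$, for the variant in
  which the work term enters the sum with a positive sign; it is not the
  default because minimizing it drives nodes against the applied load.)

## Discretization in tangent space

The centerline is divided into $N-1$ elements of nominal length $l$ with
nodes $\mathbf{x}_0 \dots \mathbf{x}_{N-1}$ and nodal tangents
$\mathbf{t}_0 \dots \mathbf{t}_{N-1}$. The tangent field is interpolated
linearly on each element, which makes

$$U_e \;=\; \alpha \sum_{i=1}^{N-1} \frac{\lVert \mathbf{t}_i -
\mathbf{t}_{i-1}\rVert^2}{h_i}$$

exactly (the factor $\tfrac12$ that sometimes appears in front of the rod
energy is absorbed into $\alpha$, which is a free material parameter; only
the ratios $\alpha : \kappa : \lVert\mathbf{f}\rVert$ affect the minimizer).
Positions follow from the tangents by the trapezoid rule, which is exact for
the piecewise-linear interpolant:

$$\mathbf{x}_i = \mathbf{x}_{i-1} + \tfrac{h_i}{2}
(\mathbf{t}_{i-1} + \mathbf{t}_i),$$

or in stacked form $\mathbf{x} = B\,\mathbf{t} + \mathbf{c}$ with $B$
block-lower-triangular, diagonal blocks $(h_i/2) I_3$, hence nonsingular
(`assemble_B()`).

The *sheath* that fixes the entry direction at the insertion site becomes the
boundary condition: $\mathbf{x}_0$ and $\mathbf{t}_0$ are fixed, and the
unknowns are the $3(N-1)$ components of $\mathbf{t}_1 \dots
\mathbf{t}_{N-1}$. Every energy term is then an explicit quadratic form
$\tfrac12 \mathbf{t}^\top H \mathbf{t} + \mathbf{g}^\top \mathbf{t} + c$
(`elastic_quadratic()`, `contact_quadratic()`,
`external_work_quadratic()`), stationarity reads $A\mathbf{t} = \mathbf{b}$
with $A = \sum H_k$, $\mathbf{b} = -\sum \mathbf{g}_k$, and one dense
Cholesky solve (plus a step of iterative refinement) yields the new
equilibrium. $A$ is symmetric positive-definite whenever $\alpha > 0$: the
bending form restricted to the unknowns is positive-definite once
$\mathbf{t}_0$ is fixed, and the penalty forms are positive semidefinite. We
solve in tangent space and reconstruct positions afterwards; composing with
$B^{-1}$ and solving for positions instead is algebraically identical (the
package keeps that composed route as a cross-check test on small systems)
but would require inverting $B$ explicitly.

Two deliberate consequences of this formulation are worth stating plainly:

* **Tangents are not constrained to unit norm.** A linear system cannot
  enforce $\lVert\mathbf{t}_i\rVert = 1$, and no renormalization is applied
  afterwards — renormalizing would change the minimizer. The drift
  $\max_i \bigl|\lVert\mathbf{t}_i\rVert - 1\bigr|$ is reported as a
  per-step diagnostic instead. Its physical face is *compressibility*: when
  the tip is obstructed, some of the inserted length is absorbed by tangent
  shrinkage rather than bending. In wall-guided scenarios the drift stays
  modest (about 0.1 in the bundled curved-tube runs), but it grows when the
  rod is pushed hard against an obstruction.
* **The penalty is bilateral while a contact is active.** Each active
  contact is a quadratic spring to the triangle's *plane*, so it resists
  separation as well as penetration. Unilaterality is recovered by the
  active-set update between solves, which is why the update rule matters
  (next section).

## The equilibrium loop

Contact forces depend on positions that the solve itself changes, so a
single detect-then-solve pass cannot be self-consistent. `solve_equilibrium()`
iterates:

1. detect node-versus-triangle contacts at the current positions;
2. assemble the three quadratic forms and solve $A\mathbf{t} = \mathbf{b}$;
3. reconstruct positions and re-detect;
4. stop when the re-detected contact set equals the set just solved with
   *and* the maximum penetration changed by less than
   `active_set_tolerance` (default $10^{-6}$ mm); otherwise repeat, up to
   `max_outer_iterations` (default 50).

Setting `max_outer_iterations = 1` reproduces a single-pass variant.
Non-convergence is never an exception: the result carries
`converged = FALSE` with its residuals and the trace records it.

A node contacts a triangle when its signed plane distance is at or below the
detection margin *and* its orthogonal projection falls inside the triangle
(barycentric test, edge tolerance $10^{-9}$). The margin deserves a note: a
margin of exactly 0 releases a contact the moment the penalty has pushed the
node back to the wall plane, upon which the next solve returns to the free
shape, penetrates deeply again, and the active set oscillates without
converging. The solver therefore keeps a small positive *retention band*
(default 0.05 mm) so that resting contacts stay active. The band must remain
well below the element length: nodes within the band are held onto their
contact planes by the bilateral spring, and if many consecutive nodes fall
inside it the rod is dragged and artificially compressed. `run_config()`
therefore scales the default as $\min(0.05, l/10)$ mm, which keeps fine
discretizations (down to $l = 0.125$ mm in the bundled sweeps) consistent
with coarse ones. `detect_contacts()` itself defaults to margin 0 —
contact only on true penetration — since the retention band is a property of
the solver loop, not of detection.

Collision detection is node-based, exactly as the energy is: one penalty
term per penetrating (node, triangle) pair, several terms if a node
penetrates several triangles at a crease. The default implementation tests
all pairs with vectorized arithmetic, which at this package's scales (a few
hundred nodes against a few thousand triangles) costs about a millisecond
per call; an AABB-grid broad phase (`method = "grid"`) is available and
tested to agree exactly with brute force given the same finite contact
reach. Tunneling between nodes is the known blind spot of node-based
detection; configurations should keep $l$ below the vessel radius (and the
input step below $l$, which the driver enforces).

## Push, pull, and re-discretization

Inputs arrive as signed arc-length steps $h$ (positive push, negative pull)
with $|h| \le l$. The base element absorbs them: it grows by $h$, and when
it would exceed $l$ a new node is inserted at the sheath with tangent
$\mathbf{t}_0$ and the base element wraps around (mirror rules for
retraction). Total inserted length is therefore exact bookkeeping,
$\sum_i h_i$ equals the initial length plus the signed sum of inputs to
within round-off, and all energy integrals use per-element lengths $h_i$ so
that the single partial base element is handled consistently. After each
re-discretization the solver computes the new equilibrium; the work term's
reference positions $\mathbf{x}_{i0}$ are the previous equilibrium.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `alpha` | bending constant (energy·mm) | 1 | sets the energy scale; only ratios matter |
| `kappa` | wall modulus (energy/mm²) | 100 | sweep 10–10⁴ halves penetration per decade |
| `segment_length` (l) | element length (mm) | 1 | accuracy/speed trade-off; keep below vessel radius |
| step h | input step (mm) | script | must satisfy `abs(h) <= l` |
| `margin` | contact retention band (mm) | min(0.05, l/10) | see above |
| `active_set_tolerance` | penetration-change tolerance (mm) | 1e-6 | convergence of the outer loop |
| `max_outer_iterations` | active-set cap | 50 | 1 = single-pass variant |

No physical units are imposed beyond millimeters for length: $\alpha$ and
$\kappa$ are working units, and all behavior-critical analyses in the test
suite sweep $\kappa$ rather than rely on a default.

## Synthetic phantoms and what they do (not) show

`make_tube()` generates straight and planar-curved tube phantoms (entry
straight, circular bend, exit straight, swept circular cross-section,
optionally capped) — in-silico stand-ins for the transparent plastic tubes
on which catheter simulators are commonly benchmarked. Ring vertices carry a
half-facet angular offset so that facet centers, not vertex seams, face the
bend plane; a node moving exactly in that symmetry plane then projects into
a facet rather than escaping through the seam between two tilted ones.
Normals are oriented analytically toward the centerline; for meshes loaded
from OBJ/STL files, orientation is recovered per triangle by a ray-parity
test instead.

The phantoms emulate geometry only. Real vasculature adds bifurcations,
non-circular and tapering lumens, wall compliance and motion, pulsatile
flow, and friction — none of which are modeled (the wall deforms only
implicitly through the penetration depth; the mesh itself never moves).
Passing the bundled analyses therefore demonstrates the numerics of the
solver — equivalence with a general-purpose minimizer, stationarity,
penalty behavior, discretization convergence, equivariance, determinism —
not clinical fidelity of any particular vessel.

The bundled study scenarios, also used by `scripts/acceptance.R`, are:

* *Curved-tube navigation*: lumen radius 3 mm, 10 mm entry, 90° bend of
  radius 15 mm, 20 mm exit; catheter with $l = 2$ mm inserted 6 mm and
  pushed 24 mm in 0.5 mm steps. Used for the $\kappa$ sweep
  ($\kappa \in \{10, 10^2, 10^3, 10^4\}$) and equivariance checks.
* *Obstructed tip*: capped straight tube of radius 5 mm and length 40 mm;
  base offset 1 mm off-axis and tilted 0.12 rad so the tip meets the cap
  obliquely; 62 pushes of 0.5 mm give 20+ obstructed steps over which the
  bending energy grows monotonically. (Pushing much further produces a
  physical snap-through at the cap corner where $U_e$ momentarily drops —
  visible if the script is extended.)
* *Convergence sweep*: the curved tube at $l \in \{3, 2, 1\}$ mm and
  $h/l = 1/5$, each compared against one reference solution at
  $l = \min(l)/8 = 0.125$ mm stepped at the same $h/l$. Final shapes are
  arc-length-resampled at the run's $l$ before the node-wise RMS, mirroring
  how a simulated catheter is scored against a resampled ground-truth
  curve. These sizes keep the whole sweep within a few minutes on one CPU
  core while leaving the trend (RMS decreasing with $l$) clearly resolved.

## Numerical choices and degenerate inputs

* Dense Cholesky with one iterative-refinement step; residuals
  $\lVert A\mathbf{t}-\mathbf{b}\rVert$ stay at round-off
  ($\le 10^{-10}(1+\lVert\mathbf{b}\rVert)$ is asserted).
* A non-SPD system (possible only for degenerate configurations such as
  $\alpha = 0$) raises an error naming the null direction.
* Degenerate mesh triangles (area $< 10^{-12}$ mm²) are dropped at load with
  a warning — they define no plane.
* Contacts reported on the base node are rejected with a warning: the base
  is the boundary condition, not a degree of freedom.
* Contact ordering is fixed (lexicographic in node, then triangle), every
  operation is deterministic, and reruns of a configuration produce
  byte-identical traces; trace CSVs are written with 17 significant digits
  so they parse back to identical doubles.
* Retraction past one element is refused; scripted steps larger than $l$
  are refused at configuration time.

## Known limitations

* Tangent compressibility (above): inserted arc length and reconstructed
  polyline length diverge under hard obstruction; monitor
  `tangent_norm_drift`.
* The penalty strength is per contact *node*, so refining $l$ increases the
  number of springs along a pressed segment; with the retention band scaled
  as described this had no visible effect on the converged shapes down to
  $l = 0.125$ mm, but the penalty term has no strict continuum limit.
* No torsion degrees of freedom, so coil-like devices and torque-driven
  maneuvers are out of scope; no self-collision of the catheter.
* Active-set cycling between two nearly-degenerate contact sets can exhaust
  the iteration cap on occasional steps (reported as `converged = FALSE`
  with round-off-level residuals); the quasi-static trace simply continues
  from the returned state.
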