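---
title: "gelfrac: models, discretization and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gelfrac: models, discretization and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`gelfrac` simulates quasi-static brittle fracture of thin hydrogel
structures — films, capsule membranes, scaffold sheets — represented as
membranes on triangle surface meshes. This vignette is the package's own
account of the model, the discretization, and every numerical decision a
maintainer would want to know about. It states no empirical result that
the test suite does not itself compute.

## 1. Constitutive model

**Hydrogel.** A compressible neo-Hookean energy written in principal
stretches $\lambda_i$ (singular values of the deformation gradient $F$),
with $J = \lambda_1\lambda_2\lambda_3$:
$$G(\lambda_i, J) = \tfrac{\mu}{2}\sum_i(\lambda_i^2 - 1 - 2\ln\lambda_i)
  + \tfrac{\chi}{2}(J-1)^2 .$$
Each per-stretch term and the volumetric term are nonnegative and vanish at
the reference state, which makes a clean tension/compression partition
possible: the tensile part $W^+$ collects terms with $\lambda_i > 1$ and,
for the volumetric term, $J > 1$; the compressive part $W^-$ collects the
complement. The free energy with damage is
$$W = \big[(1-K)p^2 + K\big]\,W^+ + W^-,$$
with phase field $p$ (**1 = intact, 0 = broken**, reversed relative to
much of the phase-field literature) and residual $K$. Degrading only $W^+$
keeps compressed material load-bearing, which is what stabilizes shear- and
compression-dominated shell states. $K$ defaults to `1e-4`; the source
material for this model only calls for "a small value", and `1e-4` keeps
the post-fracture stiffness about four orders below the intact one without
conditioning problems.

Whether the volumetric term should be split by the sign of $J-1$ or
degraded wholesale is a genuinely open choice; the printed $J^\pm$
substitution rules imply the sign split, which is what we implement. A
consequence worth knowing: pure volumetric compression produces no
degradable energy at all.

**Stress.** Both energies are isotropic in the stretches, so the first
Piola–Kirchhoff stress assembles in the SVD frame,
$P = U\,\mathrm{diag}(\partial W/\partial\lambda_i)\,V^\top$. This formula
is exact for the *gradient* even with repeated singular values — only
tangent operators need divided-difference limits, and `gelfrac` never
assembles tangents (see §4). Ties at the split kinks $\lambda_i = 1$,
$J = 1$ are immaterial because the split is $C^1$ there (both one-sided
derivatives vanish).

**Substrate (soft tissue).** The Ogden model
$W = \frac{2\mu_{Og}}{\alpha^2}(\bar\lambda_1^\alpha + \bar\lambda_2^\alpha
+ \bar\lambda_3^\alpha - 3) + \frac{K_{Og}}{2}(J-1)^2$ with deviatoric
stretches $\bar\lambda_i = J^{-1/3}\lambda_i$. Substrate regions never
fracture: they carry $p \equiv 1$ and contribute nothing to the damage
driving energy. Reference parameters ($\mu_{Og}/\mu = 0.1$,
$K_{Og}/\mu = 1$, $\alpha = -20$) are the soft-tissue set used by all
bundled scenarios.

## 2. Membrane kinematics and the plane-stress closure

The paper-level description of the shell element ("C0 solid shell") leaves
the element internals unspecified; `gelfrac` adopts the minimal faithful
realization: a constant-strain membrane triangle. Each element stores a
reference tangent frame and 2×2 reference edge matrix; the current
in-plane map $M$ yields the in-plane stretches from the closed-form
eigendecomposition of the 2×2 metric $M^\top M$ (no per-element SVD — this
is what makes a pure-R implementation fast enough). The full
$F = M[t_1\,t_2]^\top + \lambda_3\, n N^\top$ carries the reference normal
onto the current normal scaled by the thickness stretch $\lambda_3$.

$\lambda_3$ is closed by **plane stress**: it minimizes the degraded
energy at fixed in-plane stretches, equivalently the through-thickness
Cauchy stress vanishes. For the split neo-Hookean model the stationarity
condition is piecewise quadratic in $\lambda_3$, the energy is convex in
$\lambda_3$, and the one-sided derivatives at the two kinks
($\lambda_3 = 1$ and $J = 1$) always bracket the root — so the closure is
a *single quadratic solved in closed form*, exact to machine precision and
vectorized over all elements. (The design originally called for a
safeguarded bisection/Newton; the closed form is strictly better and is
cross-checked against a 2000-point scan oracle in the tests.) The Ogden
closure has no closed form and keeps a safeguarded bisection on
$\lambda_3 \in [10^{-3}, 10^3]$, erroring if the bracket has no sign
change.

**Thickness averaging.** The damage formulation averages the tensile
energy over $N_G$ Gauss points through the thickness
($\bar W^+ = \frac{1}{N_G}\sum_I \bar W_I^+$). In the membrane model every
Gauss point sees the same $F$, so the average equals the mid-surface
value; `thickness_rule()` and `element_avg_energy()` implement the
averaging contract explicitly (and the tests assert NG-independence) so
that a future bending-through-thickness extension slots in without
interface changes.

**Bending stabilizer.** An optional discrete-hinge energy
$k_b\,g(p_e)\,(\theta - \theta_0)^2\,\|e\|^2/(A_1 + A_2)$ per interior
edge, degraded by the same $g(p)$ as $W^+$ but *not* added to the damage
driving energy — it is a stabilizer for compressed curved shells (the
sphere demos enable it with $k_b = 10^{-5}$, of the order of the membrane
modulus times thickness cubed), not a solid-shell bending model. Default
off.

## 3. Graph phase field

The damage equation at mesh vertex $i$,
$$\Big(\tfrac{4\ell(1-K)\bar W_i^+}{G_c} + 1\Big) p_i
 + 4\ell^2 \tfrac{1}{a_i}\sum_{j} w_{ij}(p_i - p_j) = 1,$$
uses the classical discrete-differential-geometry operators: cotangent
edge weights $w_{ij} = \tfrac12\sum \cot$ (one cotangent on boundary
edges) and barycentric vertex areas $a_i$ (area/3 per incident triangle).
The exact $a_i, w_{ij}$ formulas are deferred by the source material to
the discrete-geometry literature; barycentric areas were chosen over
Voronoi areas because they are always positive and partition the total
area exactly. Negative cotangent weights on obtuse triangles are kept
(standard practice); `clamp_weights` clamps them at zero for robustness
experiments, at the price of changing the operator.

Numerical decisions:

- **Symmetrization.** Row $i$ is multiplied by $a_i$, giving a symmetric
  sparse system with identical solution, solved by sparse Cholesky with an
  LU fallback; the residual is verified against `1e-10` relative.
- **Element ↔ vertex transfer.** The formulation stores one damage value
  per element but solves at vertices. `gelfrac` uses: element value = mean
  of its three vertex values; vertex driving energy = area-weighted mean
  of incident enabled elements' $\bar W^+$. This is one consistent reading
  of the under-specified mapping, and the homogeneous closed form
  $p = 1/(1 + 4\ell(1-K)\bar W^+/G_c)$ is reproduced exactly under it.
- **Irreversibility.** The equation is driven by the element history
  $H = \max_t \bar W^+$, not the instantaneous energy. The source
  formulation is silent on healing; the history field is the standard
  device and the load–unload tests verify element damage is non-increasing
  in time.
- **Bounds.** No clamping is needed in exact arithmetic (the maximum
  principle gives $0 < p \le 1$ for nonnegative weights); the solution is
  clamped to $[0,1]$ after the solve to guard against negative-weight
  artifacts, and clamps beyond roundoff are counted and reported.
- **Boundaries.** Natural (do-nothing) conditions everywhere — the vertex
  equation simply has fewer neighbor terms on the boundary.
- The phase field is solved only on vertices incident to hydrogel
  elements; all other vertices hold $p = 1$ and enter the restricted
  system as known values.

## 4. Staggered solver

Per load step: apply prescribed displacements, then alternate

1. **displacement**: minimize total energy over free nodal coordinates at
   fixed $p$ with L-BFGS-B and the exact assembled gradient;
2. **damage**: update $H$, solve the linear phase-field system at fixed
   positions;

until $\max|\Delta p| < \texttt{tol\_p}$ (default `1e-4`) *and* the
relative energy change is below `tol_E` (default `1e-8`), capped at 50
iterations (non-convergence is flagged; the run continues or aborts per
config).

Choosing energy minimization over assembled Newton tangents is deliberate:
the split model's tangent is piecewise and tedious, while the minimization
route needs only the gradient — which the envelope condition makes cheap
and clean. Because $\lambda_3$ sits at its plane-stress optimum,
$\partial W/\partial\lambda_3 = 0$, so neither the $\lambda_3$ sensitivity
nor the current-normal sensitivity (whose stress conjugate is the vanishing
normal stress) appears in the force assembly; finite-difference oracles in
the tests confirm the assembled forces to ~1e-9 relative.

The displacement gradient tolerance defaults to
$10^{-8}\mu\,A_{\mathrm{total}}$; the bundled demos set `2e-7` — at their
force scales ($\sim 10^{-3}$) that is still $\sim 10^{-4}$ relative and
about 3× faster. L-BFGS-B has a rounding plateau near
$|g| \sim 10^{-9} \times$ (energy scale); absolute force assertions in the
tests account for it.

Reaction forces are the sums of assembled internal forces (`dE/dx`) over
constrained node sets, not Lagrange multipliers. Load stepping is a plain
prescribed factor sequence; the schedule type permits non-monotone
sequences for load–unload studies (the "strictly increasing" reading of a
ramp would make unloading inexpressible, so monotonicity is not enforced).

## 5. Synthetic scenarios: what they emulate and what they do not

The generators are deterministic, desk-scale stand-ins for the source
scenarios, not reproductions of them:

- `gen_notched_plate`: SENT specimen, 2×1, slit to mid-length at
  mid-height. The slit is a *topological* slit (duplicated nodes), and the
  mesh is built as a mirrored half so symmetry is exact by construction.
- `gen_perforated_sphere_patch`: octant/quadrant of a unit sphere by
  regular subdivision of the octahedral spherical triangles (all vertices
  exactly on the sphere; far better element quality than a lat-long grid),
  with holes of radius $r/R = 0.05$ carved along a latitude circle. The
  source geometry's hole count, layout and shell thickness are not
  printed; three holes at $\theta = \pi/4$ and $t = 0.02R$ were fixed once
  as a plausible porous-capsule reading. The compression demo presses a
  polar *cap* node set (contact-patch surrogate), not the pole vertex — a
  point load nucleates damage at the loading singularity instead of at a
  hole, which says nothing about the perforation physics.
- `gen_fiber_strip`: 4×1×0.1 lattice of longitudinal fibers plus
  crosslinks — an idealization of a fibered scaffold sheet, loaded out of
  plane at the central band.
- `gen_cap_with_patch`: a *single-mesh* surrogate for a device bonded to a
  curved organ: one ellipsoidal cap with a hydrogel polar region on an
  Ogden substrate region. The original two-mesh tie contact is out of
  scope. The demo pins the apex and expands the rim radially; without the
  apex pin a membrane cap wrinkles at zero energy and nothing stretches
  (this is a membrane-model limitation, not a solver defect).

A green test on these scenarios establishes the *qualitative* fracture
phenomenology — rise/peak/drop force curves, notch-tip initiation,
$G_c$-monotone initiation displacement, hole-adjacent nucleation,
irreversibility, symmetry — at desk scale. It does **not** establish the
source scenarios' quantitative critical displacements (e.g. their
anatomical-mesh value $u_x/l = 0.829$), which depend on unavailable
geometries and unprinted increments/tolerances.

## 6. Degenerate inputs, tie-breaks, tolerances

- Triangle areas below `1e-12` and angles within `1e-9` of 0 or π are
  rejected as degenerate at mesh validation / operator assembly.
- A collapsed *current* triangle (in-plane metric eigenvalue below
  `1e-24`) raises a degenerate-deformation error naming the element.
- Repeated in-plane stretches: the spectral projector of the 2×2 metric is
  replaced by its isotropic limit when the eigenvalue gap falls below
  `1e-12·max(eig, 1)`; the force formula is continuous across the switch.
- Split ties at $\lambda = 1$, $J = 1$ are assigned to the tensile branch;
  the $C^1$ property makes the choice invisible in values and gradients.
- `h_ele/ℓ` is reported for every run and a warning issued above 1 (the
  diffuse crack needs $h_{ele} < \ell$; the bundled demos use ~0.5).

## 7. Known limitations

- Membrane-only mechanics: no solid-shell bending response; the hinge term
  is a stabilizer with a heuristic stiffness, not a validated bending
  model. Compressive wrinkling is only suppressed, not resolved.
- No contact, no follower (pressure) loads, no dynamics, no poroelastic or
  viscous effects (the fracture-faster-than-diffusion regime is assumed).
- The phase-field/element transfer and the irreversibility device are one
  consistent reading of an under-specified formulation (§3).
- Crack paths after full ligament failure can break mesh symmetry by
  bifurcation; symmetry is only guaranteed (and asserted) up to the onset
  of path selection.
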