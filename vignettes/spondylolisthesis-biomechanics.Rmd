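---
title: "Methods: parametric lumbosacral FEM of spondylolisthesis progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parametric lumbosacral FEM of spondylolisthesis progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spinefem)
```

# The scientific question

Isthmic spondylolisthesis in adolescents progresses when the mechanical
environment of the lumbosacral junction favours it: sustained compression
on the S1 growth plate modulates endochondral growth (the Hueter–Volkmann
response, which can remodel the plate into a sacral dome), and anteriorly
directed shear on the L5–S1 disc and plate promotes further slippage.
`spinefem` implements a parametric simulation pipeline in which the three
clinically predictive spino-pelvic quantities — pelvic incidence (PI),
sacral slope (SS) and slip percentage — are free inputs, and the outputs
are the normal and shear stresses those structures see in standing posture.
This vignette documents the model, its assumptions, the tunable parameters
and the numerical choices, so that a reader can judge what the package's
passing tests do and do not establish.

# Geometry and spino-pelvic parameterization

All geometry lives in a global frame with x anterior, y left, z superior
(gravity along −z); angles are measured in the sagittal x–z plane. With
signed sagittal angles, SS is the inclination of the S1 superior endplate
to the horizontal (the plate descends anteriorly in a lordotic spine — the
reason gravity shears L5 forward), PT is the angle of the line from the
bicoxofemoral axis midpoint to the S1 endplate midpoint against the
vertical, and PI, the angle between the endplate perpendicular at its
midpoint and that same line, satisfies PI = SS + PT identically. The
package computes all three from landmarks (`compute_spinopelvic_params`),
so the identity is a live invariant of the code rather than an assumption.

Two operators re-parameterize a geometry:

* `apply_pelvic_rotation(geometry, PI, SS)` performs two sagittal rotations
  about the S1 plate center: the sacro-pelvic block as a whole (sets SS;
  PI, a morphological parameter, is invariant under a rigid rotation) and
  then the pelvis relative to the sacrum (sets PI). The spine above S1 is
  deliberately left untouched: varying SS therefore tilts the sacral plate
  *under* an unchanged lumbar column, which is what makes the plate-relative
  load direction — and hence the stresses — depend on the pelvic
  parameters at all.
* `apply_slip(geometry, slip_pct)` offsets the pelvis and sacrum rigidly
  along the posteroanterior in-plane axis of the L5 inferior endplate.
  Slip is measured by the Taillard convention (AP displacement of the L5
  inferior endplate midpoint over the S1 superior endplate midpoint,
  divided by the S1 endplate AP width). The measurement is linear in the
  offset, so the operator solves for the exact offset in closed form and
  round-trips the target to machine precision. The convention is applied
  at the endplate level; measuring at the growth-plate mid-plane instead
  would shift all slip values by a constant near-unity factor and was
  judged not worth a second convention (flagged for sensitivity analysis).

Grading follows the standard Meyerding bands (25 % increments), and the
configuration classification uses configurable cutoffs — PI ≥ 60° and
SS ≥ 50° for the low-grade shear type, PT ≥ 25° for the high-grade
retroverted pelvis — because the published classification figure gives no
numeric boundaries.

Template personalization uses dual kriging with a cubic radial kernel
r³ and a linear drift (1, x, y, z). The kernel choice is the package's
own (the technique is cited in the field without one); the linear drift
guarantees exact reproduction of affine maps, which the tests exercise.

# What the synthetic reconstruction emulates — and what it does not

`generate_template_geometry` stands in for a multi-view radiographic
reconstruction. It reproduces the reconstruction's *data model* — 17
landmarks per vertebra, 11 per rib, 23 on the pelvis, with a realistic
global arrangement (body heights and widths scaled from standing height,
adolescent lumbar lordosis 50° and thoracic kyphosis 38° as template
defaults, exposed in `default_template_dims`) — and its *noise level*
(isotropic Gaussian with σ = 3.3 mm per axis, the reported average
accuracy of such reconstructions, in `generate_patient_landmarks`).
Defaults are the reference patient: age 14, height 157.2 cm, weight
45.5 kg, PI 61°, SS 52°, Grade II slip (set at 30 %, mid-band, since only
the grade is reported).

It does **not** emulate patient-specific cortical thickness, endplate
curvature, facet orientation or the true pars geometry; vertebrae are
parametric boxes with arch loops, not segmented anatomy. Consequently,
passing the qualitative campaign tests shows that the *mechanical
mechanism* (plate-relative load redirection with PI/SS, anterior stress
migration with slip) operates in a geometrically plausible model — it does
not validate absolute stress magnitudes for any real patient, and the
package deliberately makes no absolute-magnitude claims.

# Finite-element model

* **Elements.** 8-node trilinear hexahedra (2×2×2 Gauss quadrature) for
  the L4–pelvis segment; Euler–Bernoulli beams (no shear deformation — the
  formulation is the package's choice, unstated in the source literature)
  for T1–L3, ribs and pelvis struts; axial springs for ligaments and facet
  capsules. Ligaments are tension-only: a small-strain active-set scheme
  replaces shell/contact ligament models while preserving their unilateral
  character.
* **Mesh.** One conforming structured column from the sacrum base to the
  L4 superior endplate guarantees node matching across the stack: sacrum
  (nz_sacrum layers), 3-layer S1 growth plate, disc (nz_disc), 3-layer L5
  growth plate, L5 body (nz_body), disc, L4 body. The growth plates always
  carry exactly three physiological sub-zones (newly formed bone,
  transition, sensitive zone; soft, E = 12–50 MPa). The sacral dome is a
  parametric paraboloid cap (default height 3 mm, must stay below the disc
  height) added to the S1 plate interface; height 0 reproduces the
  dome-free validation configuration. Posterior arches are six-hex
  pedicle–pars–lamina loops attached to the posterior body face;
  `pars_lysis = TRUE` (the default, matching the modeled pathology)
  removes the two L5 pars elements, and the facet capsule springs attach
  on the *arch* side of the pars so the loose posterior element remains
  kinematically held — as it is in vivo — rather than floating.
* **Materials.** `default_material_library()` carries literature-typical
  values (cortical 12 000 MPa, trabecular 100 MPa, annulus 4 MPa, nucleus
  1 MPa at ν = 0.499, growth-plate zones 12–50 MPa, ligament springs
  10–20 N/mm, facet 200 N/mm), every one overridable from the YAML
  configuration. The acceptance checks are designed not to depend on the
  specific defaults.
* **Units.** mm, N, MPa; g = 9.81 m/s².

# Loading and boundary conditions

Trunk weight enters the spine level by level through a body-weight
fraction table (default: 14 % at T1 for head/neck/arms, 2.3 % per
thoracic and 2.4 % per lumbar level, ~51 % of body weight in total —
published trunk-segment distributions; fully overridable). Each level's
weight increment is applied at the segmental centroid *along the local
tangent* of the centroid polyline (central differences, one-sided at the
ends): the muscle-stabilized follower scheme, under which the internal
force accumulates tangentially down the column instead of generating the
large fictitious transverse reactions a purely vertical load train would.
The increments — not the cumulative force — are applied externally;
applying cumulative magnitudes at every centroid would count the trunk
weight once per level.

The follower directions are recomputed from the *deformed* centroid chain
and the model re-solved until the largest direction change falls below
tol = 1e−3 rad (max 25 iterations); `single_pass = TRUE` gives the
undeformed-tangent variant, since the source literature does not state
which was used. Standing posture: both acetabula fixed in translation
with torsion springs (default 1000 N·mm/rad, configurable — the cited
value is not published) on their rotations, and T1 blocked transversally
(x, y) with the vertical left free.

# Stress analysis conventions

Stresses are element-centroid values (Gauss-averaged); nodal
extrapolation is out of scope, and whether published peak values are
nodal or element quantities is unstated — the element convention is used
consistently. The analysis frame has its origin at the centroid of the L5
growth-plate node cloud, z′ along the plate normal opposite gravity and
y′ the anterior sagittal direction projected onto the plate. Then
σₙ = σ′_z'z' (negative = compression, the growth-modulation signal) and
τ_slip = σ′_z'y', chosen among the shear components because it is the one
that drives anterior slippage: it is positive exactly when the traction on
the superior face of the plate points anteriorly.

Regions (anterior, posterior, lateral-left/right, dome) are assigned
within each structure's transverse footprint — coordinates are centered on
the structure's element centroid before splitting, because the structure
itself translates posteriorly in the L5 frame as slip grows, and the
regional statements in the underlying study refer to locations *on the
plate*. Laterality uses a type-1 quantile with ≥ so that tied |x′| columns
of a structured grid stay whole (default: top 30 % of |x′|); the dome is
the top 20 % of plate elevation with a strict inequality, so a flat plate
has an *empty* dome region, which the summary flags as missing rather than
dropping. Regional *means* are the resolution-stable summary — regional
maxima are single-element concentrations whose region assignment flips
with element size — so cross-resolution comparisons and the slip-trend
checks use means (or structure-wide maxima), not per-region maxima.

# The simulation campaign

The full 2³ factorial over PI, SS and slip has 8 cases; the packaged
default campaign is a 10-case constrained table spanning four low-grade
configurations (Grade II slip; from the nutcracker PI 52/SS 45 to the
shear PI 75/SS 60 morphology, with two intermediate cases interpolated by
the package) and six high-grade configurations (60 % and 80 % slip at
PI 60/75 × SS 45/60, including the retroverted-vs-balanced contrast). The
original constraint equations are not published; `apply_design_constraints`
therefore accepts user predicates, and the default table is an explicit
reconstruction, not a recovered artifact. Campaign responses per case:
structure-wide extrema and means of σₙ and τ_slip for the S1 growth plate
and the L5–S1 disc, their anterior-region statistics, and the anterior
offset of the top-decile |τ_slip| elements within each structure.
`campaign_stats` runs one-way ANOVA (response grouped by one factor's
levels at a time — the grouping convention is the package's choice) and
Pearson correlation at α = 0.05, with an optional Bonferroni correction
that is off by default to mirror the original analysis.

Determinism: the pipeline contains no random numbers (the seed is recorded
and only feeds the optional landmark-noise emulation), so identical
configuration and seed reproduce outputs bitwise.

# Numerical choices

* Sparse symmetric assembly (triplets → `Matrix::sparseMatrix`), Cholesky
  factorization of the free-DOF stiffness, relative residual tolerance
  1e−8 (violations raise an error naming likely missing constraints).
* Factorizations are cached per tension-only active set, so follower
  iterations that do not change the set reuse one factorization.
* Tension-only active set: springs inside a ±1e−9 mm elongation dead band
  keep their state; if a full update revisits a previous set, only the
  single most-violated spring flips (this resolves the two-state cycles
  that borderline springs otherwise produce); a revisit after a
  single-flip raises an oscillation error.
* Rotational DOFs exist only at beam-bearing nodes; a boundary condition
  on a nonexistent DOF is an error, not a silent no-op.
* Hexahedron Jacobians are checked at build time (`check_mesh_jacobians`)
  and at every stiffness evaluation; non-positive Jacobians abort with the
  element id.
* Degenerate inputs error explicitly throughout: coplanar/duplicate
  kriging controls, zero-width endplates, collinear plate nodes, constant
  vectors in the correlation, all-identical ANOVA observations.

# Problem sizes

The packaged campaign meshes each case at nx = ny = 12 in-plane elements
(about 3 200 elements and 12 000 DOF per case), a resolution at which the
ten cases solve in a few minutes on one CPU and the regional stress
pattern is stable under refinement (the cross-resolution test compares
nx = 6 against nx = 8). Unit tests use coarser meshes (nx = 6) because
they exercise contracts, not convergence.

# Known limitations

* Linear kinematics and linear elasticity only: an 80 % slip is meshed in
  its slipped configuration, but the *response* to load is small-strain;
  no contact, no material nonlinearity, no dynamics.
* Growth is not simulated: the package computes the stress *stimulus* on
  the growth plate, not the Hueter–Volkmann growth response or dome
  formation over time.
* One parametric anatomy: findings are statements about the template
  family, not about any patient population.
* The thoracic spine and rib cage are deliberately coarse (beams); they
  exist to deliver a realistic load path to L4, not to be analyzed.
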