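---
title: "A reduced finite-element model of the proximal carpal row"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced finite-element model of the proximal carpal row}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carpalfem)
```

## The biomechanical question

Scapholunate dissociation is the most common pattern of carpal instability,
and the scapholunate interosseous ligament (SLIL) — the short ligament
joining scaphoid and lunate — is regarded as the primary stabilizer of that
joint. `carpalfem` builds a *reduced* computational model of the structures
that govern scapholunate mechanics: the distal radius (cortical shell,
cancellous core, articular cartilage), the scaphoid and lunate with their
proximal cartilage, the capitate as the representative of the distal carpal
row, a network of one-dimensional ligament springs, and a
three-dimensional SLIL block bridging scaphoid and lunate.  The package
supports two kinds of question:

* *mechanistic*: what does the complex do under prescribed wrist motions,
  and what happens when the SLIL is removed?
* *metrological*: what linear stiffness do uniaxial tension tests on SLIL
  samples yield, and how does it compare with literature values?

## Surrogate anatomy

The package does not ship subject geometry.  `generate_reduced_wrist()`
builds parametric surrogate bones as superellipsoid solids on a structured
latitude/longitude grid, with a smooth seeded radial perturbation (default
amplitude 0.05 mm) standing in for anatomical irregularity.  Default
dimensions (semi-axes of a few mm for the carpals, ~11 mm for the distal
radius, a 2 mm scapholunate gap, 0.8 mm cartilage) are of the order of an
adult human wrist.  Cartilage layers are radial extrusions of the articular
caps and *share their base vertices with the bone*, so bone–cartilage
junctions are tied by construction and need no contact search; the SLIL
block is a lattice whose end faces reuse scaphoid and lunate surface nodes
for the same reason.  (Across the SLIL end faces the facet diagonals of the
two sides may differ; the interface is node-conforming, which is what the
assembly requires.)

What the surrogate deliberately does **not** emulate: real articular
congruence, cortical thickness variation, ligament insertion footprints,
and inter-subject shape variability.  Consequently every *pressure
magnitude* computed on the surrogate is geometry-specific; the package
treats printed-constant reproduction and structural *patterns* (energy
partition, mechanism behaviour) as transferable, and absolute simulated
pressures as not.

Ligament attachments follow the nine-row stiffness table (N/mm): dorsal
intercarpal 150/150, dorsal scapholunate 230, long radiolunate 75, radial
arcuate 40, radial collateral 10, radioscaphocapitate 50, short
radiolunate 75, and the volar radioscapholunate row, which expands into
radius–scaphoid and radius–lunate branches at 50.75 each.  Two rows are
anatomically surprising as tabulated (a "short radiolunate" connecting
radius and scaphoid; the oddly precise 50.75): the table is implemented *as
printed*, with `stiffness_table` overrides for users who want a corrected
network.  Landmarks are chosen on the dorsal/volar/radial half-space named
by each ligament, pointing toward the partner bone, and snapped to surface
vertices.

## Meshing

`tetrahedralize()` converts a watertight surface into tet4 elements by
stacking scaled copies of the boundary toward an interior kernel point and
splitting the resulting prisms with an index-based diagonal rule, so the
construction is deterministic and the outer boundary reproduces the input
surface exactly.  This is valid for star-shaped domains — which all
surrogate parts are — and is not a general-purpose mesher; concave
geometries would need an external tool.  Element orientation is repaired by
vertex swap rather than rejection.

Quality control implements the classical meshing rules: triangle aspect
ratio `2 r_in / R_circ` (normalized so an equilateral triangle scores 1),
tet quality `3 r_in / R_circ`, a slenderness rule (longest/shortest edge,
default threshold 10), a minimum-quality rule (default 0.1) and a gradation
rule limiting adjacent element-size ratios (default 2).  The thresholds are
package defaults: the meshing rules are stated qualitatively in the
literature this model follows, without numbers.

## Materials

Bone is isotropic linear elastic; cartilage and SLIL are compressible
two-parameter Mooney–Rivlin solids with energy

$$W = C_1(\bar I_1 - 3) + C_2(\bar I_2 - 3) + \tfrac{K}{2}(J-1)^2,$$

using deviatoric invariants $\bar I_1 = J^{-2/3} I_1$,
$\bar I_2 = J^{-4/3} I_2$.  The volumetric coefficient is taken as $K/2$ so
the small-strain bulk response equals the bulk modulus $K$; the source
material tables specify $K$ but not the volumetric prefactor, and this is
the standard convention.  Defaults (MPa): cartilage $C_1 = 4.1$,
$C_2 = 0.41$, $K = 19.3$ (from $K = E/(3(1-2\nu))$ at $E = 11.6$,
$\nu = 0.4$); SLIL $C_1 = 832.4\times10^{-6}$, $C_2 = 11.05\times10^{-6}$,
$K = 9.19802$.  The SLIL bulk modulus is stored as the printed constant:
its stated derivation ("bulk/shear ratio of 1000" with $\mu = C_1 C_2$) is
dimensionally inconsistent, although the arithmetic chain
$1000 \times 832.4 \times 11.05 \times 10^{-6}$ does reproduce the printed
value, so the constant is kept as-is and documented rather than re-derived.

Bone moduli deserve a caveat.  The tabulated values are cortical
$E = 18$ MPa, $\nu = 0.2$ and cancellous $E = 100$ MPa, $\nu = 0.25$ —
three orders of magnitude below the usual cortical stiffness
(~18 GPa), and *softer than the cancellous core*.  The library stores the
tabulated values as `cortical`/`cancellous` and additionally provides
`cortical_literature` ($E = 18\,000$ MPa).  For the cancellous-influence
study the package defaults to the literature value: with a core stiffer
than its shell, the stiffer interior necessarily attracts load and no
parameter-free argument can make the cancellous contribution small, whereas
the literature-scale shell reproduces the expected behaviour (see below).
The choice is a configuration argument (`cortical_entry`), not a hidden
rewrite of the table.

## Boundary conditions from wrist motions

The proximal face of the radius is fully fixed.  Wrist motions are taken
from the range-of-motion table (flexion 65–80°, extension 55–75°, radial
deviation 15–25°, ulnar deviation 30–45°; pronation/supination stored but
not simulated because they do not engage the scapholunate joint) at the
range midpoint by default.  A rotation by $\theta$ about the wrist centre is
converted to a uniform cartesian translation of all capitate nodes — the
distal carpal row moving as a rigid solid with the capitate — along the
chord of a circle of radius $r$:

$$u_\text{tangential} = r\sin\theta,\qquad u_\text{axial} = -r(1-\cos\theta),$$

with the tangential axis and sign set by the motion (extension $-y$,
flexion $+y$, radial $-x$, ulnar $+x$) and the axial displacement always
proximal ($-z$).  The lever arm defaults to $r = 19.40$ mm, recovered by
least squares so that the conversion reproduces the published capitate
displacement table to within 0.02 mm on all eight entries
(`fit_lever_arm()` performs the fit; the package treats the reconstruction
as the implemented formula since the original conversion is not spelled
out).  The prescribed translation is ramped linearly over the load steps.

## The solver

The FEM core is a total-Lagrangian tet4 solver: constant-gradient elements,
analytic first Piola–Kirchhoff stress for Mooney–Rivlin, small-strain
kinematics for the linear bone materials (which makes the patch test exact),
axial springs with their exact material+geometric tangent, and optional
frictionless node-to-triangle penalty contact.  Element tangents for the
hyperelastic elements are central finite differences of the exact analytic
internal force (12×12, symmetrized), which keeps the code compact while the
test suite verifies tangent/residual consistency to 1e-4 and Newton's
superlinear contraction.  Numerical choices:

* convergence: relative residual 1e-6 with absolute fallback 1e-9 N,
  at most 25 iterations per step;
* load stepping: linear ramp, with up to 3 step bisections on failure;
* a backtracking line search halves the Newton increment while it would
  invert an element or raise the residual norm — essential because the SLIL
  material is about four orders of magnitude softer than bone, so the
  tangent is very ill-conditioned and full Newton steps can overshoot
  through the soft modes;
* linear solves by sparse LU (`Matrix`); problem sizes are desk scale
  (the default carpus is ~800 nodes / ~3200 elements at a 3 mm target
  edge — sizes chosen so the full stability study runs in well under a
  minute);
* divergence is a *result*, returned as a structured record
  (step, iteration, residual norms), not an error.

`detect_mechanism()` assembles the tangent at the reference configuration
with boundary conditions applied and counts eigenvalues below
`tol * max(eigenvalue)`.  The default `tol = 1e-11` is calibrated by scale
separation, not tuned to a particular run: genuine rigid (mechanism) modes
sit at the numerical-zero floor, around $10^{-15}$ of the largest
eigenvalue, while the softest *elastic* modes of the default model — SLIL
flexure — sit above $10^{-9}$ of it, leaving more than three orders of
magnitude of margin on either side of the threshold.

## The two headline studies

**Cancellous influence.**  `run_reduced_radius_study()` meshes the radius
alone, fixes its proximal face, applies unit pressure patches on the two
articular fossae of the distal cartilage, solves, and partitions strain
energy by region.  With the literature-scale cortical shell the cancellous
core carries a fraction of the elastic energy that is orders of magnitude
below the cortical share, and the largest displacements occur on the loaded
cartilage itself — the quantitative form of the argument for modelling each
bone as a single cortical piece.

**SLIL removal.**  `slil_stability_study()` compares the intact and
SLIL-less carpus in two independent ways: the mechanism mode count at
reference, and a Newton solve under a *probe* load (default 1% of the full
extension displacement, over 4 steps).  The probe magnitude is a deliberate
design decision.  A mechanism is a property of the tangent at the reference
state: an under-constrained complex has unresisted rigid freedoms and fails
(or drifts) at *any* load level, so a small probe already separates the two
configurations cleanly.  Driving the full ~18 mm motion instead entangles
the stability question with a different, known artifact: ligament forces
concentrated at single attachment nodes of a very soft bone locally
overload and invert elements — single-node attachments are an acknowledged
limitation of 1D ligament modelling, and full-magnitude runs remain
available through `run_pipeline(motion_fraction = 1)` with that caveat.  On
the default surrogate the intact model shows 0 mechanism modes and
converges; removing the SLIL leaves 5 near-zero-energy modes (the combined
scaphoid+lunate pair retains 12 rigid freedoms against at most 8 distinct
spring constraints) and the probe solve fails.

## Pressure reporting

"Pressure" is the hydrostatic part of the Cauchy stress with **compression
positive**, $p = -\operatorname{tr}\sigma/3$; the opposite convention is
equally common, and the choice here matches reporting separate
max-compression and max-traction values.  Whether a contact pressure was
meant instead of hydrostatic stress is not decidable from the source
material; hydrostatic stress is implemented and this note records the
alternative.  Internal units are consistent mm–N–MPa; pressures are
converted to Pa exactly once, at the reporting layer
(`region_envelope()`, `max_compression_traction()`).

## The stiffness experiment

`fit_linear_stiffness()` estimates the linear stiffness of a uniaxial
load–displacement curve as the least-squares slope over a window of the
displacement range, defaulting to the upper 60% so the nonlinear toe region
is skipped (the original fit window is not documented; this default is the
package's choice and is configurable).  `summarize_stiffness()` uses the
sample (n−1) standard deviation — the convention that exactly reproduces
the printed 39.00 N/mm from the six printed sample values, where the n
denominator would give 35.6.  The pooled literature value 65.50/34.70 is
stored as a printed constant: the midpoint-of-ranges reading reproduces the
mean exactly but the standard deviation only approximately (34.75), so it
is never used as a computed check.  `synthesize_curve()` generates toe-plus-
linear curves with Gaussian force noise for testing; parameter-recovery
tests run 200 seeded replicates at 1 N noise and require the mean fitted
slope to be within 1% of truth.

```{r stiffness-example}
s <- summarize_stiffness(slil_stiffness_samples())
s
compare_to_literature(s)
```

## Known limitations

* The tetrahedralizer requires star-shaped watertight surfaces.
* Prescribed motion is a rigid translation along the rotation chord, not a
  true rotational boundary condition about an anatomical axis.
* Ligaments attach at single nodes; attachment regions concentrate force.
* No dynamics, friction, viscoelasticity, anisotropy or damage.
* All simulated pressure magnitudes are specific to the surrogate geometry
  and are reported as patterns, not as reproducible constants.
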