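---
title: "Methods: electro-quasistatic comparison of PFA catheter designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electro-quasistatic comparison of PFA catheter designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Model

Pulsed-field ablation lesions form where the electric field magnitude
exceeds a lethal electroporation threshold. At PFA pulse time-scales
(microseconds) tissue capacitive effects are negligible, so the field at
any instant obeys the electro-quasistatic volume-conductor equation

$$\nabla \cdot \big(\sigma(|\nabla\varphi|)\, \nabla\varphi\big) = 0,$$

with Dirichlet potentials on energized electrode surfaces and zero normal
current on the outer boundary (except a grounded skin return patch for
monopolar deliveries). Because the equation is instantaneous, quantities
such as *the fraction of delivered power reaching a target* and *the
current needed to exceed a field threshold over 90 % of a target* are
properties of catheter geometry and vectoring alone — no pulse width,
repetition or train structure enters. This is what makes a fair comparison
of devices with undisclosed waveforms possible, and it is the design
principle of this package: nothing in the core ever sees time.

### Assumptions

- Ideal tangential contact: electrodes touch the endocardial surface
  without displacing tissue; all designs are centred on the same target.
- Inactive electrodes are removed from the system (tissue-adjacent no-ops)
  rather than modelled as floating equipotential conductors. This is a
  simplification; floating metal would locally channel some current.
- Electrode-electrolyte interface impedance, thermal effects and
  electrochemistry are out of scope; ECD is the standard proxy for the
  latter two.

## Synthetic anatomy

The phantom replaces a CT-derived thorax with the minimal geometry the
three metrics depend on: wall curvature, a blood pool on the endocardial
side, a fixed wall thickness, and a distant return path. A cylindrical vein
(radius 10 mm) opens into a spherical blood chamber (radius 20 mm); the
myocardial shell is the set of points within 2.5 mm of the blood pool,
measured on an exact signed-distance function, so the wall thickness is
nominal along every surface normal by construction. Everything else is
connective background. The target is the full-thickness wall band of arc
length 47 mm and axial width 6 mm (nominal volume
$6 \times 47 \times 2.5 = 705\ \mathrm{mm^3}$) on the posterior vein wall.

Default spacing is 0.5 mm (five voxels across the wall); the complete
six-design sweep is also run at 1.0 mm (two to three voxels across the
wall) as a smoke configuration, which preserves the ranking. Tests use
slab phantoms at 0.25–0.5 mm for geometry-sensitive checks.

What the phantom does *not* emulate: surrounding organs (esophagus, aorta,
lungs), anatomical asymmetry, wall-thickness variation, and the sheer size
of a thorax. Consequently absolute efficiencies and currents differ from
what a CT-derived model yields — the phantom's blood pool is smaller and
the return path shorter — and the package never claims them. The
comparison's acceptance surface is the *ordering* of the six designs plus
the in-table arithmetic, not absolute values.

### Conductivities

The default table (S/m): blood 0.70, myocardium 0.20, connective
background 0.10, balloon insulator $10^{-5}$. These are round values from
standard tissue-property compilations; only their ratios drive the
comparison and every entry is overridable (YAML-serializable).

Electroporation makes myocardial conductivity field-dependent. The model
is a monotone sigmoid

$$\sigma(E) = \sigma_0 \Big(1 + \frac{A}{1 + e^{-(E - E_{mid})/k}}\Big),$$

with defaults $A = 2$, $E_{mid} = 500$ V/cm, $k = 80$ V/cm for myocardium
only. The literature on tissue electroporation consistently reports a
conductivity *increase* on permeabilization, so the default fold change is
positive, but the sign of $A$ is configurable because published modelling
work is not unanimous on the direction used. With $A = 0$ the tissue is
linear and the solver short-circuits to a single solve.

## Catheter models

All six designs are rasterized into blood voxels adjacent to the wall, in
surface coordinates (arc length along the circumference, axial offset,
depth into the lumen). Published dimensions are the defaults: circular
decapolar rings 3 mm × 1.6 mm (nominal 3.7 mm gaps; on the default vein
circumference the closed loop forces the slightly smaller uniform pitch of
C/10 ≈ 6.3 mm), penta-spline rings 1.3 mm × 3 mm with 3/3/4 mm gaps and all
four rings of a spline as one electrical node, flex/balloon electrodes
3.6 × 3.6 mm every 6 mm on 4 mm splines, 0.127 mm Nitinol struts for both
spheres. Struts thinner than a voxel are rasterized to one-voxel chains —
this preserves the field topology (mesh openings) — and the ECD denominator
always uses the analytic metal area, never the inflated voxel area.

Design-specific choices where the sources give no number:

- **Focal 9 mm sphere**: mesh cage (meridians/parallels every 30°) with a
  flattened 6 mm contact cap (rings + spokes), matching the 6 mm
  application step along the band (7 placements, each an independent
  solve).
- **One-shot sphere**: six diamond-mesh panels. The deployed sphere
  (nominal 30 mm) is larger than the vein, so panels touch the wall only
  along the equatorial contact line and stand off it with the sphere's
  sagitta $a^2/2r$ at axial offset $a$; the diamond pitch is one third of
  the undeformed panel width (≈ 5.2 mm). Both features matter physically:
  the standoff exposes most panel metal to blood and the open mesh produces
  the Faraday cage effect (field suppression under opening centres), which
  the test suite checks explicitly.
- **Balloon vs flex splines**: identical electrode layout; the balloon
  additionally fills the lumen behind the electrodes with insulator voxels.
  This single structural difference is what drives their efficiency gap.
- **Return patch**: 60 × 60 mm on the boundary face farthest from the
  target. On a compact phantom the patch's access resistance (through the
  0.1 S/m background) is a non-negligible series term: a small 42 mm patch
  shows ~20 % efficiency sensitivity under area doubling, while at 60 mm the
  patch effectively fills the far face and further enlargement changes
  monopolar efficiency by < 10 % (verified by a sensitivity test). The
  default is therefore the face-filling size.

### Vectoring

A *vector* is one sourcing (positive) electrode with its return. Circular:
one delivery with interlaced alternating ring polarities. Penta-spline:
bipole from each spline to its neighbour, rotating five times per
application, two applications rotated 36°. Flex/balloon: one axial
(−, +, −) tripole per spline, four splines, second application rotated 45°.
Spheres: monopolar to the patch, per placement (focal) or per panel
(one-shot). Only deliveries near the posterior target are counted in the
metrics, with the published per-design counts (one-shot 3, focal sphere 7,
penta-spline 6, circular 3, flex/balloon 8); the counted deliveries are
those whose sourcing electrode is nearest the band centre. Deliveries not
counted on target are also not solved: on this phantom their contribution
to the posterior band is negligible, and skipping them saves about 40 % of
the solves.

## Solver

Finite-volume 7-point discretization on the uniform voxel grid with
harmonic-mean face conductivities (conservative across material
boundaries, the standard choice for voxel conductors); Dirichlet values
±V/2 on active electrodes; Jacobi-preconditioned conjugate gradients
(compiled core, relative residual $10^{-8}$). Field-dependent conductivity
is handled by Picard iteration with under-relaxation 0.7, σ evaluated at
cell-centred field magnitudes (central differences), stopping when the
maximum relative σ change drops below $5\times10^{-3}$ (at most 50
iterations; non-convergence raises an error carrying the update history).
Current control: linear runs are solved once at unit voltage and scaled
exactly; nonlinear runs wrap the Picard loop in a secant iteration on the
applied voltage, started from the linear estimate, to a relative current
tolerance of $10^{-3}$.

Discrete conservation identities — net Dirichlet current ≈ 0, face-summed
Joule power = Σ I·V — hold to the linear residual and are asserted at 1 %
and 2 % in the tests. Degenerate inputs (all-insulator path, single-polarity
delivery, empty electrode rasterization) raise errors rather than returning
silently wrong fields.

### Validation against closed forms

Because no published absolute field values are reproducible at desk scale,
the solver is validated against analytic solutions: the parallel-plate
uniform field (exact to $10^{-6}$), and the spreading resistance of a
voxelized spherical electrode inside a grounded spherical shell. The shell
(rather than the domain box) is used as the ground so that an exact closed
form $(1/a - 1/b)/(4\pi\sigma)$ exists: against it the error is purely
discretization and must shrink monotonically when the spacing halves,
which the suite checks at 0.5 → 0.25 mm; against the infinite-medium form
$1/(4\pi\sigma a)$ the same solve agrees within 10 % at 0.5 mm.

## Metrics and search

Transmurality uses the literal volume rule: the fraction of target voxels
whose per-voxel maximum field across counted deliveries exceeds the
threshold (600 V/cm, configurable). The maximum (union) rule across
sequential deliveries is the standard electroporation-dose assumption for
identical sequential pulses. The current for 90 % transmurality is found by
bisection on [2, 70] A to 1 % relative width; for linear tissue the probe
rescales one reference solve per delivery, and the result is checked
against the quantile-scaling closed form
$I^\* = I_{ref}\,E_{th}/E_{(k)}$ (the k-th largest reference field in the
target, $k = \lceil 0.9\,N\rceil$). A level unreachable at 70 A is
reported as "not achieved", not thrown. Efficiency sums target power and
delivered power over the counted deliveries before dividing
(power-summed); a per-delivery-averaged variant is available, and the two
coincide for a single delivery. ECD and ECD×N are reported with the
published rounding (integers; currents to one decimal).

The comparison configuration defaults to linear tissue: both ranking
metrics are either scale-invariant (efficiency under linear conductivity)
or checked against the linear closed form, and the field-dependent model
mainly rescales the current axis without reordering designs; the nonlinear
path is exercised by its own tests and available via `nonlinear = TRUE`.

## Problem sizes

The test suite and the acceptance script run the full six-design sweep on
the 64 × 64 × 72 mm antrum phantom at 1.0 mm (≈ 3 × 10^5 voxels, 28 counted
solves, a few minutes on one CPU); solver validation runs at 0.5 mm with a
single 0.25 mm refinement solve (≈ 2.5 × 10^6 voxels). The 0.5 mm
comparison (≈ 2.4 × 10^6 voxels) is the documented full configuration for
standalone use.

## Known limitations

- Idealized contact and anatomy: no contact-force variation, no
  respiratory motion, no wall-thickness heterogeneity; conclusions are
  about inherent design properties, not clinical lesions.
- Inactive electrodes do not float; see above.
- The one-shot panel strut layout is parametric (pitch, height, strut
  width), not traced from a specific device; the cage-effect property is
  required to hold for the defaults.
- Voxel rasterization of 0.127 mm struts inflates their geometric
  cross-section to one voxel; field topology is preserved but near-strut
  field magnitudes are resolution-limited.
- Absolute efficiencies and currents are phantom-specific; only orderings
  and table arithmetic are comparable to published values.
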