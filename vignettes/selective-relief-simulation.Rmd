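---
title: "Selective relief of palatal plates: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective relief of palatal plates: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palaterelief)
```

## The problem

A removable plate denture rests on the palatal mucosa.  Where the mucosa
is thin or pain-prone, the plate's tissue-facing (intaglio) surface is
hollowed out by a fraction of a millimetre — a *relief* — so that the
plate does not press there.  Because modern framework materials are hard
to adjust after fabrication, the relief must be designed beforehand, and
practice varies widely: conventionally a standard strip is relieved along
the palate midline.

This package simulates an alternative, *selective* strategy: solve the
stress field of the fully bonded plate under the bite load first, then
relieve exactly the interface regions where mucosal von Mises stress
reaches a cutoff (the *borderline*) or higher.  Strategies are compared
by a volume metric: for each stress threshold, the volume of mucosa
stressed at that level or higher, expressed as a percentage of the same
volume in the no-relief model.

## The mechanical model

The model is a bilayer: a resin plate bonded to the oral surface of a
mucosa layer whose other side adheres to bone.

* **Kinematics/material.** Small-strain, homogeneous, isotropic linear
  elasticity in both parts.  No contact, no time dependence, no material
  nonlinearity.  Units are mm-N-MPa throughout.
* **Plate.** E = 2650 MPa, ν = 0.3 (wet denture base resin).
* **Mucosa.** E and ν are free parameters — the measured subject values
  behind such studies are not public.  Defaults are E = 8 MPa, ν = 0.37;
  see *Calibration* below.
* **Restraint.** The bone-side mucosa surface is fully constrained
  (adhesion to the maxilla).
* **Load.** The pain-onset bite force, 111 N, acts vertically onto the
  center of the plate's oral surface.  A true point load would make the
  near-field stress singular and every threshold volume mesh-dependent,
  so the force is distributed over a patch (default radius 3 mm) with
  tributary-area nodal weights; the weights sum to the total force
  exactly, and an infinite radius reproduces uniform pressure exactly.
* **Bond.** Plate and mucosa share interface nodes (adhesion condition);
  no relative displacement across a bonded interface.

### Finite elements

Both parts are meshed with 4-node constant-strain tetrahedra.  The mesher
is a structured mapped grid: a regular footprint grid whose node columns
follow the three surfaces (plate oral surface, interface, bone), with
`ceil(thickness / mesh_edge)` element layers through each part (minimum 2
through the mucosa, 1 through the plate), each hexahedral cell split into
six tetrahedra along a consistent main diagonal.  This guarantees a
conforming interface — the bonded condition costs nothing — at the price
of no boundary-fitted unstructured meshing, which the simple parametric
geometry does not need.  The element stiffness uses the standard
Lam&eacute;-form kernel; assembly is vectorized into sparse triplets; the
reduced system after exact row/column elimination of prescribed DOFs is
solved by sparse Cholesky factorization, with a 1e-8 relative-residual
guard and reaction recovery `K u - f`.  Stress is constant per element;
the von Mises scalar is `sqrt(3/2 s:s)` of the deviatoric part.

Verification built into the test suite: element stiffness against an
independent `B^T D B` oracle; rigid-body null space; the patch test
(prescribed linear fields reproduced to machine precision on box and
bilayer meshes); a uniaxial closed form (uniform von Mises and face
displacement `pH/E` to 1e-8); global equilibrium to 1e-6 relative on
every solve; refinement convergence at an interior probe.

### Relief as interface decoupling

Relief of depth 0.25 mm is realized not by re-meshing the trimmed plate
but by *decoupling*: every interface node touched by a relieved facet is
duplicated, and plate tetrahedra are re-wired to the duplicates.  In a
linear model with an open gap no force can cross the relieved area, so
decoupling is mechanically equivalent to the geometric trim while keeping
all scenarios on the same mesh (volumes stay exactly comparable).  The
equivalence assumes the gap stays open; after each relieved solve the
relative normal approach of plate towards mucosa is checked at every
duplicated pair, and a warning names the scenario if it ever exceeds the
relief depth (it does not, under the default conditions).  Whether the
original procedure trimmed only the plate or also re-meshed the mucosa is
not decidable from the outside; decoupling is this package's reading, and
it is exact for the quantity of interest (mucosal stress under an open
gap).

Element stress is projected to interface facets conservatively: a facet's
value is the maximum von Mises over all mucosa tetrahedra touching any of
its nodes, so anything in contact with super-threshold stress is
relieved.  Relieving the entire interface leaves the plate with no load
path and is reported as a singular system naming the floating part.

### The study driver

`run_study()` executes, in order: the no-relief solve; for each
borderline (defaults 0.04, 0.06, 0.08, 0.10, 0.14 MPa) region selection
**from the no-relief field**, decoupling, and a re-solve — a single pass,
never iterated on the post-relief field; and the conventional mid-palatal
strip (10 mm wide).  Seven scenarios by default.  The analyzed stress
interval is 0.02–0.20 MPa; distributions are reported at thresholds
0.02, 0.04, …, 0.20 MPa, both cumulatively (volume at the threshold *or
higher*, the headline representation) and as disjoint bins, since "volume
at a stress value" admits either reading.  Ratios against the no-relief
baseline are undefined where the baseline volume is zero and are reported
as `NA`, never silently as 0.

## The synthetic palate

No subject geometry or measured thickness map is public, so the package
generates a parametric stand-in:

* **Footprint** 44 × 45 mm (mesial of the first molars to distal of the
  second molars), midline at x = 0.
* **Vault** — a cosine arch of height 10 mm across the width, constant
  along the arch; height 0 degenerates to the flat slab used by solver
  verification fixtures.
* **Thickness map** — 14 segments (7 rows × left/right), one thickness
  each, drawn uniformly within per-segment bounds by a seeded generator
  and blended bilinearly across the segment-center grid, so the sampled
  value is recovered at each center and the field is smooth and
  deterministic.  Default bounds span 1.0–6.0 mm, thin in the mid-arch
  rows and thicker towards the borders.
* **Raphe band** — a Gaussian midline groove (45% thinning, 3 mm
  half-width, configurable, `raphe_thinning = 0` disables) multiplies the
  blended field.  The two-column segment grid cannot represent the thin
  midline raphe, yet that band is the anatomical reason mid-palatal
  relief exists; without it no load-bearing contrast between the palate
  center and the lateral slopes can arise, whatever the segment values.
  The groove factor is 0.9994 at the segment centers, so center fidelity
  is preserved.
* **Mesh** — target edge 0.5 mm by default.  The shipped analysis scripts
  and the acceptance workflow run at 1.5 mm (≈ 21,600 elements, ≈ 14,400
  DOFs), which resolves the stress pattern the relief decisions depend on
  while keeping a full seven-scenario study around a minute; the
  refinement study in the test suite shows the probe stress converging.

What the generator does **not** emulate: real vault cross-sections vary
along the arch; rugae, tori and glandular tissue are absent; thickness is
measured vertically, not along the surface normal; mucosa is in reality
nonlinear, layered and rate-dependent.  Tests passing on this geometry
therefore validate the *procedure* (solver, selection, decoupling,
metrics) and the *direction* of the relief effects, not subject-specific
percentages, which depend on an individual's geometry and tissue data.

### Calibration of the free parameters

The study design pins the analyzed stress interval to the no-relief
model: its endpoints, 0.02 and 0.20 MPa, bracket the stresses the bonded
model generates under the 111 N pain-onset load, and all five borderlines
lie inside it.  The mucosa modulus is the free parameter that sets this
scale, and it was calibrated once so that the default synthetic model
reproduces the condition: with E = 8 MPa (a plausible tangent modulus for
keratinized palatal mucosa at pain-onset strain) and ν = 0.37 (the usual
denture-FEA soft-tissue value), the no-relief field spans the interval
with a small super-0.20 tail across seeds, so every borderline selects a
non-empty region and the 0.20 MPa ratio is defined.  Near-incompressible
settings (ν → 0.5) suppress deviatoric stress in the confined thin layer
and cannot reach the upper half of the interval at any plausible
modulus.  Both values remain configurable and are echoed in every report.

## Numerical choices

* Thickness sampling uses an isolated RNG stream (the session `.Random.seed`
  is restored), so `(config, seed)` fully determines the geometry and the
  whole study is bit-reproducible.
* Degenerate inputs: non-positive thickness anywhere aborts meshing;
  collapsed thickness bounds are legal (deterministic thickness); a
  mid-palatal width below one facet selects the nearest facet row with a
  warning; an empty relief region returns the input mesh unchanged, making
  a borderline above the peak stress an exact identity (ratios exactly
  100).
* Region masks are nested by construction across increasing borderlines;
  the facet projection uses `>=`, so a borderline of 0 relieves the whole
  interface (and is then rejected as a singular system).
* Mesh I/O uses ASCII VTU with 17-significant-digit coordinates so a
  write/read round trip is exact; part labels are mandatory on read.

## Known limitations

Gap closure is detected but not resolved (no contact mechanics); relief
depth enters only through that check, not the stiffness.  Single-pass
selection follows the original procedure — iterating relief on the
post-relief field is deliberately out of scope.  The structured mesher
cannot grade element size locally.  Stress percentages from any one
geometry — including the shipped default — are geometry-dependent; only
the directional comparisons are claimed, and they are exactly what the
acceptance workflow recomputes.
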