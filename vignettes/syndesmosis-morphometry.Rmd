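---
title: "Measuring the distal tibiofibular syndesmosis in 3-D: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the distal tibiofibular syndesmosis in 3-D: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syndesmo3d)
```

## The measurement problem

Radiographic assessment of the distal tibiofibular syndesmosis — the fibrous
joint between the distal tibia and fibula — traditionally measures the
tibiofibular clear space (TCS) and tibiofibular overlap (TFO) at a fixed
height (commonly 1 cm) above the tibial plafond. Anatomy, however, varies:
the lateral prominence of the anterior tibial tubercle, which is what makes
the overlap measurable at all, sits at different heights in different people
and differs systematically by sex. A fixed measurement level therefore
compares different anatomy across subjects.

This package implements an individualized alternative in 3-D:

1. **Plane X** — the tibial plafond plane, fitted to the distal articular
   surface of the tibia.
2. **Point A** — the lateral prominence of the anterior tubercle, defined by
   the intersection of tangent lines along the tubercle, found at the level
   where the incisura fibularis is deepest.
3. **Plane Y** — the plane through point A parallel to plane X; its height
   above plane X is the parameter **XY**.
4. In plane Y: **point B** (fibular point nearest A), **point C** (posterior
   tubercle corner, same tangent construction), **point D** (fibular point
   nearest C), **point E** (deepest point of the incisura). These give
   **TCS-A** = |AB|, **TCS-P** = |CD| and **IFD** (perpendicular distance
   from E to line AC).
5. **Point F** — the proximal tip of the incisura, tracked section by
   section; **IFH** is its height above plane X.
6. A simulated anteroposterior radiograph (parallel projection along the AP
   axis) yields radiographic **TCS** and **TFO** at the plane-Y level, and a
   radiographic IFH.

All constructions run on triangulated bone surfaces ("mesh path") or on
CT-like volumes ("voxel path") that are first segmented with the standard
post-processing chain: density threshold at 150 HU (values equal to the
threshold count as bone), removal of 26-connected components smaller than
500 mm³ (strictly less than), sub-voxel isosurface extraction at the
threshold level, and seeded bone labeling standing in for the operator's
interactive clicks.

## Operationalized constructions

Published descriptions of interactive measurements leave several steps
underdetermined; the package pins them down as follows.

**Plafond plane.** From a seed on the distal articular surface, a patch is
grown across mesh faces whose normals stay within 30° of the seed face's
normal, limited to a 25 mm geodesic radius (centroid-hop approximation); a
total-least-squares plane is fitted to the patch vertices and oriented
proximally. Patches below 50 faces abort with an explicit error.

**Tubercle corners.** On a plane-Y cross-section the incisura appears as a
concavity of the tibial contour. The opening chord is the convex-hull edge
bridging the deepest concavity; the corner on each side is the intersection
of the supporting line along the tubercle's outer flank (the adjacent hull
edge) with the chord line, snapped to the nearest contour vertex within
1 mm — the landmark must lie on bone. When the tubercle's top runs exactly
along the chord (possible in degenerate synthetic sections), the corner is
where the contour leaves the chord. The construction is isolated in
`tubercle_corner()` so alternative readings of the tangent-line definition
can be swapped in.

**Choice of the measurement level.** The level search scans candidate
heights above plane X (default window 4–20 mm, step 0.625 mm, one slice
spacing) and scores each by the concavity depth of the tibial section —
the IFD at that level. This operationalizes the verbal criterion that the
measuring plane carries the maximal clear space / incisura depth: of the
candidate definitions we considered, section depth is the only one that is
monotone in the prominence of the tubercles *and* computable from the tibia
alone (the radiographic overlap needs the fibula, whose position should not
influence a tibial landmark). Ties break toward the most distal level. A
golden-section refinement (`refine = TRUE`, tolerance 1 nm) follows the
coarse scan, so that on analytic surfaces the recovered level is exact
rather than quantized to the scan step.

**Point E.** The deepest point of the notch is searched over the concavity
arc between the two corners (we assume E is constrained to that arc; the
alternative — a global search over the whole contour — would latch onto the
medial bone body, which is farther from line AC than any notch point).

**Point F.** The notch is tracked upward from plane Y in 0.5 mm sections;
F is the deepest notch point at the most proximal section whose concavity
depth still exceeds 0.5 mm, refined by bisection on that predicate. The
0.5 mm floor separates a true incisura from surface ripple on segmented
data; it is exposed as `notch_min_depth` (and must be scaled when the
geometry is rescaled, as the scale-equivariance tests do). If the notch
persists to the top of the volume, an explicit error is raised.

**Radiograph.** The projection is orthographic along −y (non-weight-bearing
AP view): the film-focus geometry of the original radiographs is not
reported, and a parallel beam keeps the simulation deterministic; this is a
stated fidelity limit, and magnification is unmodeled. Bone silhouettes are
stored as per-row horizontal extents computed from exact mesh cross-sections
(piecewise linear in height), which is strictly more accurate than scanning
rays at a fixed pitch; a dense ray-casting oracle in the test suite checks
agreement to 0.2 mm. The lateral border of the *posterior* tubercle is
occluded by the anterior tubercle in a pure outline; on film it is a
tangency edge visible inside the bone shadow, and is operationalized by
projecting the tibial surface posterior to a sagittal split (`y_split`,
default 0 in the canonical frame). Radiographic IFH is the most proximal
level at which the anterior- and posterior-tubercle borders still separate
by more than 0.5 mm; with a tilted plafond this is foreshortened relative to
the 3-D IFH, reproducing the ordering reported for real radiographs.

**Frames and sides.** Everything is computed in one canonical frame
(+x lateral, +y anterior, +z proximal, right side); left ankles are mirrored
across the sagittal plane at ingest and tagged with their original side.
Anterior/posterior disambiguation uses the canonical +y axis, so inputs are
expected roughly patient-aligned; rigid-motion invariance is guaranteed (and
tested, at 10⁻⁶ mm) for the moderate pose rotations (±15°) a positioned CT
exhibits, not for arbitrary reorientations that invert anatomical axes.

## The phantom: study conditions with analytic truth

Real reference cohorts are not redistributable, so validation runs on a
parametric phantom with analytically known ground truth for every parameter.
Its defaults are the study conditions: 0.625 mm isotropic voxels, bone at
700 HU and soft tissue at 40 HU (either side of the 150 HU threshold), and
`phantom_preset()` carries the published sex-specific group means — male
XY 12.1, TCS-A 2.8, TCS-P 3.6, IFD 5.1, IFH 35.1, TFO 5.5 mm; female 7.8,
1.8, 2.9, 4.2, 33.7, 3.8 mm.

The anatomy family is the simplest smooth one in which all seven parameters
are independently controllable:

* **Tibia** — a superelliptical tube (semi-axes 10 × 14 mm, exponent 2.5)
  whose lateral aspect carries two tubercle ridges bounding a V-shaped
  incisura notch. The V profile (straight walls from each tubercle tip to
  the deepest point) keeps the anterior tip blunt enough (≈ 48°) to survive
  voxelization; a circular-arc notch would leave a razor-thin wedge that
  erodes by several voxels. The notch depth follows a piecewise-linear tent
  in height: slope 0.35 mm/mm at the peak — exactly at the requested XY,
  which is what makes the measurement level identifiable at voxel
  resolution — descending to 0.5 mm exactly at the requested IFH (with a
  steeper 1.5 → 0.5 mm run over the last 3 mm so the closure level stays
  localizable under voxel-scale ripple), then fading to zero. All slope
  breaks coincide with mesh knot rings, so the linearly interpolated mesh
  realizes the profile exactly. The distal cap at height 0 is the flat
  plafond; the talus (an ellipsoid) sits below it.
* **Fibula** — an elliptical tube (semi-axes 6.5 mm mediolateral × 11 mm
  anteroposterior; the large AP axis gives the medial face the gentle
  curvature of a real fibular ridge). Its centre and the posterior tubercle
  tip are solved numerically at generation time so that TCS-A, TCS-P and
  TFO are realized *exactly against the discretized ring polygon* — truth is
  defined on the geometry the meshes actually carry, which is what makes
  10⁻⁶ mm truth-consistency attainable. The stub spans only the syndesmotic
  segment (plane Y −5 mm to +3 mm): proximally the incisura becomes too
  shallow to clear a full-length shaft, and nothing above that segment is
  measured. Infeasible requests (e.g. a TFO too large for the tubercle
  geometry, or tibia–fibula clearance below the voxel-separability margin)
  raise explicit errors rather than clipping.
* **Voxelization** uses a partial-volume edge model: per-voxel occupancy
  fractions from exact scanline crossings (three sub-rows per voxel row),
  mapped linearly to HU between soft tissue and bone. This emulates the
  partial-volume effect that makes sub-voxel isosurface extraction
  meaningful on real CT; a binary rasterization would quantize the surface
  to ~0.6 mm staircase ripple and defeat every sub-voxel contract. Debris
  blobs (spurious components below 500 mm³) are placed ≥ 5 mm from any bone
  at deterministic positions; noise is additive Gaussian, clipped at
  −1000 HU.

What the phantom does **not** emulate: trabecular texture, cartilage,
soft-tissue contrast, scanner PSF anisotropy, pathology, or the anatomical
covariance between parameters (none is documented, so presets treat them as
independent and `phantom_random()` samples them independently within the
published normal ranges, rejection-sampling into the feasible region of the
family). Passing tests therefore demonstrate correctness of the geometric
constructions and the segmentation chain under controlled conditions, not
clinical performance on real scans. One linked simplification: the family
ties radiographic TCS to the same fibula that realizes TCS-A/TCS-P/TFO, so
the implied radiographic TCS (3.5 mm male, 2.5 mm female) is below the
published means — radiographic TCS is not a controllable truth parameter
here.

The rater-table simulator draws a two-way crossed design
`y[i,j] = mu[i] + r[j] + e[i,j]` and *standardizes* each drawn effect vector
to its specified SD (a conditioned draw). With three raters the raw realized
rater variance has two degrees of freedom and would scatter so widely that
an ICC computed from the table could sit anywhere within ±0.06 of the target
— useless for validating the estimator. The conditioned draw makes the
realized variance components exact while remaining Gaussian in shape.

## Statistics

Reliability and comparison statistics are computed from explicit formulas
(base fitters like `aov()`, `lm()` and `t.test()` serve as independent
oracles in the test suite only):

* **ICC(2,1)** — two-way random effects, absolute agreement, single
  measurement: `(MSR − MSE) / (MSR + (k−1)MSE + (k/n)(MSC − MSE))` from the
  two-way ANOVA mean squares. The 95% interval is the exact F construction
  for this form with Satterthwaite denominator degrees of freedom (the
  source only names a 95% CI; this is the standard choice for the
  absolute-agreement single-measure form, documented in `?icc_2_1`).
* **RMS-SD** — the root mean square of per-subject SDs across repeats,
  `sqrt(sum(SD²)/N)`, sample SDs with n−1. Sessions four weeks apart are
  treated as independent repeats for intra-rater precision.
* **ANCOVA** — `value ~ sex + height`, extra-sum-of-squares F for the sex
  term, adjusted means at the grand-mean height. Rank deficiencies name the
  offending term.
* **Paired t** — classic paired t with two-sided p; zero-variance
  differences report exact equality rather than failing.
* No multiple-testing correction is applied by default, matching the
  original analysis; `p.adjust()` can be applied downstream.

## Numerical choices

* Threshold comparison is `>=` (a voxel exactly at 150 HU is bone);
  component-volume comparison is strict `<` ("less than 500 mm³").
* Isosurfaces: marching tetrahedra (six-tet Kuhn split, linear interpolation
  at the level crossing), watertight away from the grid boundary; the grid
  is padded by one background layer so boundary-touching masks still close.
  No smoothing is applied — smoothing biases gap distances.
* Connectivity is 26-neighbour in 3-D, the most permissive standard choice.
* Contours below 1 mm² are discarded as tangency slivers.
* Distances to contours are computed against edges (continuous), never
  vertices only; landmark searches are verified against dense brute-force
  resampling at 0.01 mm to within 0.05 mm.
* Degenerate inputs raise errors naming the failure (no incisura at a
  level, fibula absent from plane Y, plane outside volume, articular patch
  too small, zero total variance, constant covariate).

## Problem sizes used in validation

The test suite measures the male and female reference phantoms at full ring
density (~40 000 tibial faces) on both paths, sweeps 100 random feasible
phantoms at reduced density (~6 000 faces; the truth is defined on the
discrete geometry, so reduced density changes cost, not correctness), and
uses 2 000 × 3 simulated rater tables for the estimator checks. The
acceptance script regenerates both reference phantoms at full density and
reports the recovered parameters.

## Known limitations

* Orthographic projection and unmodeled magnification in the simulated
  radiograph; beam-angle mis-positioning is only explored as a sensitivity
  property, not corrected for.
* Seeded labeling stands in for the original interactive segmentation; real
  tibio-talar contact may require the optional erosion-based separation
  that this package does not implement (bones in the phantom never touch).
* Anterior/posterior identification assumes approximately patient-aligned
  input frames.
* The phantom family cannot represent an os trigonum, incisura shape
  variants (C- vs Γ-shaped), or fractured anatomy.

## A worked example

```{r example, eval = FALSE}
ph <- generate_phantom(phantom_preset("male"), voxelize = FALSE)
rec <- measure_surfaces(ph$surfaces, articular_seed = c(0, 0, 0),
                        subject = "male_ref")
rec
#  3-D row:        XY 12.1, TCS-A 2.8, TCS-P 3.6, IFD 5.1, IFH 35.1 (mm)
#  radiograph row: TFO 5.5, TCS 3.48, IFH 34.0 (mm)

plot_landmarks(attr(rec, "landmarks"),
               slice_contours(ph$surfaces[c("tibia", "fibula")],
                              attr(rec, "plane_y")))
```
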