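---
title: "Measuring overeruption and tipping of unopposed molars in 3D"
author: "molarDrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring overeruption and tipping of unopposed molars in 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molarDrift)
```

## The measurement problem

When a molar loses its antagonist — typically because the opposing tooth
was extracted ahead of implant therapy — it can drift: it erupts further
toward the now-empty occlusal space and it tips, usually in the
bucco-lingual direction. Quantifying that drift over the months between
extraction and the definitive restoration requires comparing two CBCT
scans of the same jaw taken under different head positions, which means
three coupled sub-problems: building comparable surface models from the
two volumes, superimposing them on anatomy that did **not** move, and
expressing the residual motion of the target tooth in a clinically
meaningful, tooth-local coordinate system.

molarDrift implements that chain as testable components:

1. **Segmentation.** Each tissue class (crown/enamel, root/dentin,
   alveolar bone) is thresholded into its own binary mask over a
   half-open intensity interval `[lo, hi)`, the masks are united by a
   voxelwise OR, a spherical window is opened in the bone mask around the
   target root apexes so the root is visible in the combined model, and
   the union is meshed at iso-level 0.5 by marching tetrahedra.
2. **Registration.** The follow-up model is superimposed onto the
   baseline with point-to-point ICP (closed-form SVD/Kabsch update per
   iteration), restricted to the stable alignment area: all crowns of
   the dentition except the target tooth, plus alveolar bone away from
   the alveolar crest and the opened window.
3. **Coordinate frame.** On the baseline model, the occlusal plane is a
   total-least-squares fit through the cusp tips of the posterior teeth
   of the quadrant; the z-axis is the perpendicular to that plane through
   the midpoint of the segment joining the mesial and distal
   marginal-crest midpoints (Mm, Md); the origin is where the z-axis
   meets the plane; +x points mesial, +y lingual, +z occlusal.
4. **Metrics.** With CC the centroid of the cusp tips and CA the
   centroid of the root apexes, the tooth axis is the unit vector from CA
   to CC. Per cusp, dz is the z-displacement between timepoints;
   `OE_mean` is their mean (equivalently the z-displacement of CC) and
   `OE_max` their signed maximum with the attaining cusp reported.
   The bucco-lingual tipping angle is
   `BLT = asin(axis . y)` in degrees (angle between the axis and the
   mesio-distal plane, positive toward lingual) and
   `MDT = asin(axis . x)` (positive toward mesial); the outcome
   parameters are the changes `cBLT` and `cMDT` between timepoints, both
   measured in the baseline frame. Negative `cBLT` is buccal tipping.
5. **Statistics.** One-sample t against zero for each outcome, one-way
   ANOVA across molar types, frequency/percentage descriptives, and the
   repeatability protocol: Dahlberg's combined method error
   `sqrt(sum(d^2) / 2n)` over duplicate measurements and the two-way
   mixed, single-measure, *consistency* intraclass correlation
   coefficient, ICC(3,1).

## The synthetic phantom and what it stands for

Patient CBCT pairs are not publicly deposited, so every stage is
exercised on a two-timepoint phantom with known ground truth. The
phantom defines its own right-handed mm coordinate system (x mesial, y
lingual, z occlusal; the occlusal axis is part of the construction, so
ground truth is never derived). Its geometry is chosen so that all
landmarks exist in closed form:

* the target crown is a superellipsoid (exponent 4) carrying 2-5
  spherical cusps whose tips — sphere top points — are exact landmarks,
  all at one height so the baseline tooth axis is exactly occlusal;
* 1-3 roots are tapered cones with analytic apex points;
* the alveolar bone is a ridge with an undulating cortical top, flaring
  undulating lateral plates and an undulating inferior border — the
  undulations emulate the non-planar cortical contours of real bone, and
  they matter numerically: any large axis-aligned plane in a binary mask
  reconstructs at half-voxel-quantised positions, which would bias the
  registration;
* two stable neighbour crowns sit one tooth pitch (9.5 mm) mesial and
  distal, a smaller one mesially and a larger one distally, each with a
  small axial inclination as posterior teeth have in a real arch (their
  cusp spheres stay upright so the quadrant cusp tips remain exactly
  coplanar for the occlusal-plane fit).

Tissue classes get strictly ordered mean intensities (background 0 <
bone 400 < dentin 900 < enamel 1600, arbitrary units) so midpoint
thresholds separate adjacent classes; optional Gaussian intensity noise
emulates scanner noise. Geometric truth is never perturbed by the
intensity noise — operator landmark error is modelled separately by
`jitterLandmarks()`.

**Motion composition (fixed order, tests depend on it).** The target
tooth first rotates about CA, then translates by the eruption amount
along the occlusal axis; finally the whole jaw (tooth and stable
structures alike) undergoes a rigid jaw transform emulating the
different head position of the second scan. The tooth rotation is the
*minimal* rotation taking the occlusal axis z to the direction
`(sin(mdTip), sin(blTip), sqrt(1 - sin^2 - sin^2))`. With this
construction the measured `cBLT`/`cMDT` equal `blTip`/`mdTip` exactly
even when both tips are nonzero; composing two elementary rotations
instead would couple the two angles by about 0.15 degrees at 10/10
degrees, an avoidable ambiguity in what "ground truth" means. For a
single nonzero tip the construction reduces to a rotation about the
mesio-distal (or bucco-lingual) axis through CA.

What the phantom does **not** emulate: enamel/dentin texture, beam
hardening and metal artefacts, soft tissue, partial-volume intensity
ramps, patient-specific anatomy, or any DICOM-level scanner behaviour.
Passing the recovery tests therefore shows the *measurement chain* is
correct and numerically stable at CBCT-like resolution — not that
segmentation thresholds transfer to any particular scanner.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| voxel spacing | 0.25 | mm | CBCT-like; scans in this application are acquired at 0.1-0.3 mm slices and 0.125 mm pixels; 0.25 keeps a two-jaw-segment volume around 10^6 voxels |
| crown height / root length | 7 / 13 | mm | molar-like proportions; the CA-CC lever arm (about 20 mm) sets how landmark noise converts to angle noise |
| cusp radius | 1.2 | mm | molar cusp scale; tips are sphere tops |
| threshold ranges | class-mean midpoints | intensity | the phantom stand-in for scanner-specific "experience thresholds"; half-open intervals partition adjacent classes exactly |
| apical window radius | 4.5 | mm | covers all root apexes of the default 3-root tooth |
| crest margin | 2 | mm | depth of the excluded alveolar-crest band below the local bone top |
| boundary margin | 1 | mm | strips mesh faces created where structures are cut by the volume border, tested in both timepoints' frames |
| ICP tolerance / max iterations | 1e-6 mm / 200 | | RMS-change stopping rule; non-convergence is flagged, not an error |
| ICP restarts | 6 x 0.4 deg | | see numerical notes |
| landmark jitter | 0 (pipeline studies use 0.05) | mm per coordinate | operator digitisation error |

## Numerical choices

* **Total least squares for the occlusal plane** ("matching all the cusp
  tips" names no criterion): the normal is the smallest singular vector
  of the centred tip matrix — deterministic, and exact for coplanar
  tips. The target tooth's own cusps are included in the fit (a flag
  drops them).
* **Iso-level 0.5 on the binary mask**, not on intensities, so
  segmentation and meshing stay decoupled. Meshing is marching
  tetrahedra on the Kuhn 6-tetrahedron cell subdivision, which is
  conforming across cells and yields watertight surfaces; masks are
  zero-padded first so structures touching the volume border still close.
  The iso-surface of a binary mask sits half a voxel outside the
  outermost inside voxel centres — area/volume checks account for that.
* **Point-to-point ICP with exact nearest neighbours** (uniform-grid
  accelerated, bit-identical to brute force). Correspondence is
  vertex-to-vertex, not point-to-surface — a documented limitation that
  adds noise of the order of the vertex spacing. Because
  vertex-sampled staircase surfaces create shallow local minima a
  fraction of a degree from the best fit, the pipeline uses
  `icpAlignRobust()`: converge, then re-initialise from six 0.4-degree
  rotations of the solution and keep the basin with the lowest RMS.
* **Sign conventions**: clinical summary tables report signed means,
  which forces a sign convention on "angle between axis and plane";
  positive is taken toward lingual (BLT) and mesial (MDT), matching the
  axis directions, so buccal tipping is negative `cBLT`. `OE_max` is the
  signed maximum (an intruding tooth has negative `OE_max`), and ties in
  cusp attribution break in the fixed order MB, DB, ML, DL, B, L.
* **Frame reuse**: the coordinate frame is built once on the baseline
  landmark set and reused for the follow-up measurement, so frame error
  largely cancels in the change scores.
* **ICC form**: "two-way mixed model" does not pin down
  absolute-agreement vs consistency; the single-measure *consistency*
  form ICC(3,1) is used, and the offset-invariance test documents the
  choice (a constant between-session offset does not reduce it).
* **Percentages** are rounded half-up to two decimals, mirroring the
  style of clinical sample-characteristic tables; raw values are kept.
* **Degenerate inputs** fail loudly: collinear plane points, Md
  projecting onto the origin, coincident lingual/buccal centroids,
  label mismatches between timepoints, zero within-group variance in
  ANOVA, zero between-subject variance in ICC.

## Design choices where the design was open

* **Mm/Md are inputs, not detected**: no algorithm is given in the
  source methodology for locating marginal-crest midpoints, and cusp
  tips were digitised by an operator; the package treats all landmarks
  as inputs and models operator error explicitly.
* **The apical window is spherical** with explicit centre/radius; the
  clinical workflow shows a window but never parameterises it. Because
  the tooth moves between timepoints, the two models' windows sit at
  different anatomical positions after superimposition — the alignment
  area excludes *both* window regions in *both* models.
* **Manual mask edits are replaced by label-based subtraction**: the
  commercial workflow's "remove part of cusps / remove the crown part"
  steps are operator edits; the phantom pipeline achieves the same
  separation through per-voxel structure labels.
* **The "treatment evaluation mode" of the commercial registration tool
  is undocumented**; equivalence cannot be asserted, so the package
  validates ground-truth recovery instead, which is the property the
  measurement actually needs.

## Repeatability protocol in silico

`methodErrorStudy()` mimics a two-session repeatability study: each
phantom subject is measured twice with independent landmark jitter, and
Dahlberg's error plus ICC(3,1) are computed per parameter. With 4 cusps,
per-coordinate jitter of SD `s` per session gives `OE_mean` a session
error SD of `s/sqrt(2)` (two centroids of four tips), so the default
`s = 0.1 mm` targets a Dahlberg error of about 0.07 mm — the scale a
careful operator achieves on real scans. Ten subjects spanning the
clinically observed `OE_mean` range give between-subject variance far
above that error, hence ICC well above 0.95; with only 10 duplicate
pairs the Dahlberg *estimate* itself fluctuates by roughly 20%.

## Problem sizes and runtime

The recovery studies use: 200 random motions on the landmark-exact path
(machine-precision recovery, seconds); 20 random motions through the
full voxel pipeline at 0.25 mm spacing (about 10^6 voxels and 2 x 10^5
mesh vertices per timepoint, roughly 10 s per subject); and coarser
0.4-0.8 mm phantoms in unit tests. These sizes were chosen so the whole
suite runs on a laptop-class single core in a few minutes while the
voxel resolution stays in the CBCT range.

## Known limitations

* Rotation about the tooth's long axis is not an outcome parameter (the
  methodology defines none), although the phantom can generate it as
  part of a jaw transform.
* Vertex-to-vertex ICP correspondence, no point-to-plane refinement.
* The phantom's stable structures are rigid by construction; real bone
  remodels, and crowns can be restored between scans — violations of the
  stable-area assumption are not modelled.
* Real negative-`OE_mean` cases co-occurring with large buccal tipping
  are reproduced qualitatively by pure-tipping phantoms (a tipped crown
  lowers its cusp centroid), but the cohort-level association is a
  clinical observation, not an invariant of the geometry.

## A minimal session

```{r, eval = FALSE}
spec <- PhantomSpec(voxelSpacingMm = 0.25, seed = 1)
motion <- GroundTruthMotion(eruptionMm = 0.5, blTipDeg = -2,
                            jawRotation = axisAngleRotation(c(0, 1, 0), 3),
                            jawTranslationMm = c(1, -0.5, 0.8))
res <- runPhantomPipeline(spec, motion, jitterSdMm = 0.05, seed = 1)
res$drift            # measured OE_mean / OE_max / cBLT / cMDT
res$expected         # ground truth implied by the motion
res$jawRecoveryError # how well ICP undid the jaw transform

cohort <- simulateCohort(nTeeth = 30, seed = 2)
oneSampleT(cohort$OE_mean)
oneWayAnova(cohort, "OE_mean")
methodErrorStudy(nSubjects = 10, jitterSdMm = 0.1, seed = 3)
```
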