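# molarDrift

Three-dimensional measurement of the positional change of **unopposed
molars** — teeth whose antagonist has been extracted — from CBCT-style
volume pairs. The package is written for researchers in craniofacial
imaging/morphometrics who need a tested, scriptable version of the
clinical measurement chain, and it ships a synthetic two-timepoint molar
phantom with known ground-truth motion so every stage is verifiable
without patient data.

## The method

Two scans of the same jaw (baseline T_o before the antagonist is
extracted, follow-up T_n before the restoration) are turned into
comparable surface models and compared in a tooth-local frame:

* **Multi-threshold segmentation** — binary masks for crown, root and
  alveolar bone over half-open intensity intervals `[lo, hi)`, a Boolean
  union, a spherical *apical window* opened in the bone mask to expose
  the target root, and marching-tetrahedra meshing of the union at
  iso-level 0.5 (STL export, per-vertex region labels in a sidecar).
* **Masked rigid superimposition** — point-to-point ICP (SVD/Kabsch
  update, exact nearest neighbours) restricted to the stable alignment
  area: all crowns except the target tooth plus alveolar bone away from
  the alveolar crest, the opened window and the volume border.
* **Tooth coordinate frame** (built on T_o) — occlusal plane as a total
  least-squares fit through the quadrant's cusp tips; z-axis
  perpendicular to it through the midpoint of the marginal-crest
  midpoints Mm and Md; origin at the axis-plane intersection; +x mesial,
  +y lingual, +z occlusal.
* **Outcome parameters** — with CC/CA the centroids of cusp tips and
  root apexes and the tooth axis the unit CA→CC vector:
  * `OE_mean` = z-displacement of CC between T_n and T_o (mm),
  * `OE_max` = signed maximum per-cusp z-displacement, with the
    attaining cusp (MB/DB/ML/DL/B/L) reported,
  * `BLT = asin(axis·ŷ)`, `MDT = asin(axis·x̂)` in degrees (positive
    lingual/mesial), and their changes `cBLT`, `cMDT` (negative `cBLT`
    = buccal tipping).
* **Statistics** — one-sample t vs zero, one-way ANOVA across molar
  types, frequency/percentage descriptives, Dahlberg method error
  `sqrt(Σd²/2n)`, and the two-way mixed single-measure consistency
  ICC(3,1) for the repeatability protocol.

## Worked example

```r
library(molarDrift)
runDemo(eruptionMm = 0.5, blTipDeg = -2, seed = 1)
```

prints (0.3 mm voxels, landmark jitter 0.05 mm, jaw moved 2°/~1.4 mm
between scans):

```
Demo phantom: eruption 0.5 mm, BL tip -2 deg, MD tip 0 deg, jaw moved 2 deg / ~1.4 mm

DriftResult
  OE_mean:   0.4827 mm
  OE_max:    0.7057 mm (cusp ML)
  cBLT:     -2.3148 deg (BLT 0.3265 -> -1.9883)
  cMDT:     -0.1004 deg (MDT 0.1298 -> 0.0294)
  registration RMS: 0.1174 mm

Ground truth: OE_mean 0.487 mm, OE_max 0.585 mm (ML), cBLT -2.000 deg, cMDT 0.000 deg
Jaw recovery error: 0.1153 deg / 0.0245 mm; ICP RMS 0.1174 mm (35 iterations)
```

Reading it: the phantom tooth truly erupted 0.5 mm and tipped 2° toward
buccal while the whole jaw also moved between scans. The pipeline
segmented both volumes, undid the jaw motion by masked ICP to 0.12°/0.02
mm, and recovered the eruption to 0.005 mm and the tipping to 0.3°
despite 0.05 mm operator-style landmark noise (the ground-truth
`OE_mean` of 0.487 differs from 0.5 because tipping slightly lowers the
cusp centroid). `OE_max` lands on a lingual cusp — buccal tipping lifts
the lingual side most, the same cusp pattern reported clinically.

A cohort-level session:

```r
cohort <- simulateCohort(nTeeth = 30, seed = 2)
oneSampleT(cohort$OE_mean)          # t, df, p against zero
oneWayAnova(cohort, "OE_mean")      # across molar types
descriptiveTable(cohort)            # counts and percentages
methodErrorStudy(nSubjects = 10, jitterSdMm = 0.1, seed = 3)  # Dahlberg + ICC
```

A thin command-line front end (`inst/cli/molardrift`) exposes the same
chain as `simulate / segment / register / measure / stats / demo`
subcommands; see the vignette `vignettes/measuring-overeruption.Rmd` for
the full method description and design rationale.

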