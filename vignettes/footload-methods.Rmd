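---
title: "Linking foot-bone architecture to regional plantar load: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking foot-bone architecture to regional plantar load: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footload)
```

## The scientific problem

In the diabetic foot, altered skeletal alignment under load is believed to
concentrate plantar pressure under specific forefoot regions, which in turn
drives ulceration risk. `footload` implements a complete analysis chain that
quantifies this link in individual patients: static, weight-bearing
three-dimensional bone architecture on one side, dynamic regional plantar
loading during gait on the other, joined by an exhaustive correlation
screen. The package also ships a synthetic generator for every input family
(bone meshes, pressure recordings, clinical records) with closed-form
ground truth, so the whole chain is testable without patient data.

## The foot anatomical reference frame

Bone surfaces arrive as STL meshes in the scanner's technical frame,
together with a segmented ground surface. The anatomical frame is built
from two landmarks and the ground:

* the **vertical axis** is the normal of the total-least-squares plane
  through the ground vertices (SVD of the centred cloud), oriented toward
  the bones;
* the **antero/posterior axis** joins the ground-plane projections of the
  most plantar points of the calcaneus and of the second metatarsal head;
* the **medio-lateral axis** is their cross product (vertical x
  antero/posterior), giving a right-handed triad.

The lateral plane is spanned by the antero/posterior and vertical axes, the
transverse plane by the antero/posterior and medio-lateral axes, and the
frontal plane by the medio-lateral and vertical axes. All meshes are
rigidly realigned into this frame, after which the ground is exactly
`z = 0`.

One detail is deliberately more conservative than the bare definition: the
"most plantar point of the second metatarsal head" is searched only in the
distal 30% of M2's longitudinal extent (using a provisional frame built
from the globally lowest vertex, then rebuilding the frame once). In
deformed feet the globally lowest M2 vertex can sit on the proximal shaft,
which would swing the antero/posterior axis off the ray of the second
metatarsal; the distal restriction pins it to the head region.

## PCA bone-embedded frames and the 84 skeletal variables

Each bone's own frame comes from the eigen-decomposition of the covariance
of its unique surface vertices about their centroid: three orthogonal axes
of maximal variance, which for foot bones align with the longitudinal,
medio-lateral and dorsi-plantar anatomical directions. Vertices are
unweighted by default; an area-weighted variant is available
(`area_weighted = TRUE`) because the surface-point phrasing leaves the
sampling measure open. Axis signs are fixed deterministically: the
longitudinal axis has non-negative dot product with the antero/posterior
axis; of the remaining two eigenvectors the one more parallel to the
vertical becomes dorsi-plantar (positive dorsal); the medio-lateral axis
completes a right-handed triad. When the two leading eigenvalues are
within a factor of 1.05 there is no dominant longitudinal direction (a
near-spherical bone); a warning is recorded and the eigen-order is kept
with a deterministic sign fix, so results remain reproducible across
numerics backends.

From the realigned frames the package derives, per foot:

* **absolute inclinations** `I3` (signed elevation of the longitudinal
  axis above the ground plane, dorsal positive), `IL`, `IT`, `IF`
  (signed angles of the axis projected into the lateral, transverse and
  frontal planes) for M1-M5 and P1-P5: 40 values;
* **relative orientations** `R3` (unsigned 3D angle between metatarsal and
  phalanx axes) and `RL`, `RF`, `RT` for the five metatarsophalangeal
  pairs: 20 values. Planar relative angles are *differences of projected
  absolute inclinations* (distal minus proximal), so `RL_MxPx = IL_Px -
  IL_Mx` holds identically and dorsiflexion is positive, plantarflexion
  negative;
* **minimum heights** above the ground (clipped at zero) for the ten
  forefoot bones plus cuboid and navicular, each also divided by the foot
  length: 24 values.

That totals 84 named variables (`I3_P2`, `RL_M1P1`, `Hg_NAV`, ...). Two
conventions deserve a note. First, the normaliser of the "relative"
heights is the foot length (the calcaneus-to-M2 plantar distance measured
in the ground plane): it is the only length scale the frame itself
provides, and it makes relative heights dimensionless and comparable
across feet; the choice is recorded in the export metadata. Second, a
longitudinal axis orthogonal to a projection plane has no defined angle in
that plane; such entries are carried as missing values and removed
pairwise in the correlation stage rather than zero-filled.

## From pressure recordings to LOAD and FUNC variables

Each trial is a time-ordered stack of 2D pressure grids (5 mm pitch, 10 ms
frame interval, capacitive-platform range 0-1270 kPa) plus footprint-plane
positions of five skin markers (calcaneus, metatarsal heads I/II/V,
hallux). The per-trial footprint is the per-sensor maximum over time; a
sensor is in contact above 10 kPa (configurable).

Regional masking reconstructs an anatomical subdivision from the markers:

* the foot axis runs from the calcaneus marker to the centroid of the
  metatarsal-head markers;
* the **whole-foot plantar angle** gamma opens at the most posterior
  contact point (the apex) between the medial and lateral tangent rays of
  the footprint; two interior rays split it into 30% / 51% / 19% of gamma,
  medial to lateral, defining the first, central (II-IV) and fifth
  metatarsal sectors;
* the **forefoot band** lies between the metatarsal-head marker line and
  the toe line (through the hallux marker, perpendicular to the foot axis,
  default posterior offset 15 mm, i.e. roughly the metatarsophalangeal
  crease); the **hallux region** is the contact anterior to the toe line
  and medial of the first boundary ray; the remaining contact is labelled
  midfoot/hindfoot by thirds of the toe-free extent.

Two numerical choices matter here. The tangent rays are computed over the
*anterior half* of the footprint: with a rounded heel, hull points adjacent
to the apex subtend angles approaching 90 degrees and would degenerate
gamma toward 180 degrees, whereas the anatomical fan runs from the heel to
the forefoot edges. And apex plus tangents are taken over contact *pixel
corners*, not centres, which tracks the continuous footprint outline to
sub-pixel accuracy (on synthetic footprints the label agreement with the
planted geometry is above 99%).

Per region the package reports, averaged over the five trials:

* `PP` - peak pressure: maximum over frames and sensors in the region;
* `PTI` - pressure-time integral of the *regional peak-pressure curve*
  (the maximum over the region's sensors at each frame, integrated over
  stance). An alternative convention - the largest single-sensor time
  integral - is exposed via `per_sensor_pti = TRUE`;
* `PTIN = PTI / CT` (contact time in seconds), in kPa. Published tables
  of contact-time-normalised integrals are not always reconstructible from
  simple division by the group-mean contact time, so no validation against
  any particular printed cohort is attempted for this variable.

`PTI` is computed per trial and then averaged - the registered-and-averaged
footprint has no time axis, so integrals cannot be computed from it.
Registration (rigid 2D alignment of contact-mask centroid and principal
axis, followed by bilinear resampling and a pixelwise mean) is retained for
the **arch index**: the toe-free footprint is divided into three
equal-length bands along its principal axis and the arch index is the
middle-band contact area over the total. **Contact time** is the number of
frames with at least one sensor above threshold, times the frame interval.

## Clinical scoring and grouping

The composite neuropathy variable `NS-VPT` is the sum of four
max-normalised contributions: MNSI history (/15), MNSI physical
assessment (/10), vibration perception threshold at hallux (/40) and at
malleolus (/40); range 0-4 in relative units. Patients are neuropathic (N)
when at least two of three conditions hold with strict inequalities:
MNSI > 2, Michigan Diabetes Neuropathy Score > 7, VPT > 25 Volt; LADA
diagnoses form their own group; everyone else is D. Which MNSI sub-score
the `> 2` cut-off refers to is genuinely ambiguous; the physical-assessment
score is used (the conventional 2-point cut-off) with a switch to the
history score.

## The correlation screen

For each group (ALL, N, D) the screen evaluates every 3D variable against
every LOAD, FUNC (contact time, arch index), BIOL (age, BMI) and CLIN
(years of disease, NS-VPT) variable - 84 x 18 = 1512 inter-variable pairs -
plus all pairs within the 3D variables (C(84,2) = 3486) and within the
LOAD variables (C(12,2) = 66). Pearson's r is computed on
pairwise-complete observations with the two-sided p-value from the t
distribution on n-2 degrees of freedom; pairs with fewer than three
complete observations or zero variance are flagged, not silently dropped.
The screen applies `p < 0.05` with *no* multiple-testing correction - it is
a screening design, and corrected inference is available via the
Benjamini-Hochberg switch but off by default. R-squared values are classed
weak (up to 0.30), moderate (above 0.30 up to 0.70) and strong (above
0.70), with half-open boundaries exactly as stated. Group contrasts use
the equal-variance Student's t-test (Welch optional). The pair counts hold
*within each group*; summaries report, per 3D-variable family
(lateral/transverse/frontal/3D angles: 15 x 12 = 180 LOAD pairs each;
forefoot heights: 240; midfoot heights: 48), the number and share of
significant LOAD correlations, plus quartiles of the significant
R-squared.

## What the synthetic generator emulates - and what it does not

**Bones** are scalene ellipsoids sampled on a latitude/longitude grid that
is closed under reflection through the three principal planes. This makes
the vertex covariance exactly diagonal in the body frame, so PCA recovers
the planted axes *exactly*, and the analytic lowest point of the posed
ellipsoid (with its reflections, preserving the symmetry) is inserted into
the triangulation, so minimum heights and the plantar landmarks that
define the foot frame are exact too. Default sizes, declinations
(metatarsals pitched head-down 10-18 degrees, hallux phalanx
plantarflexed ~11 degrees, lesser phalanges slightly dorsiflexed) and
heights are anatomically plausible for an adult foot; per-bone pose jitter
(SD 2.5 degrees, 1.5 mm) individualises seeded feet, and the whole scene
receives a random rigid "scanner" pose that the pipeline must undo.
Ellipsoids have no condyles, sesamoids or cortical detail: a perfect
geometric recovery here demonstrates the frame algebra and PCA machinery,
not robustness to realistic bone shape, segmentation noise or partial
surfaces.

**Pressure trials** rasterise a designed footprint (rounded heel, narrow
midfoot, broad metatarsal band, hallux and lesser-toe pads) at 5 mm / 100
Hz. Each region carries a floored-Gaussian spatial bump anchored at a
sensor centre and a half-sine temporal window; windows overlap so contact
spans exactly 68 frames (680 ms, a typical adult stance time). Peak
amplitudes default to typical diabetic-cohort values (e.g. 418 kPa under
the central metatarsals). By construction the planted peak pressure is
recovered exactly, the half-sine integral matches `2AT/pi` to within the
temporal discretisation (well under 2%), and contact time is exact.
Trial-to-trial jitter (2 mm, 1.5 degrees, 5% amplitude CV) emulates
natural step variation. Real pedobarographic data differ in roll-over
dynamics, sensor noise and partial footprints; small systematic biases do
appear at sector boundaries (a few percent of pressure-time integral can
leak between adjacent metatarsal sectors when a boundary pixel is
mislabelled), which is the realistic price of marker-based masking.

**Cohorts** draw all 102 analysis variables around typical published
cohort values. Planted links set
`load = slope * angle + noise` with the noise variance from the identity
`R2 = slope^2 var(angle) / (slope^2 var(angle) + var(noise))`, so the
*population* R-squared equals the target; the default link plants
R-squared 0.77 between second-phalanx 3D dorsiflexion and the
central-metatarsal pressure-time integral, mirroring the strongest
association this kind of study reports. Because the calibration is at the
population level, the *sample* R-squared at n = 200 still has a sampling
SD of about 0.029, so roughly 92% (not substantially more) of replicates
fall within 0.05 of the target - a property worth remembering when reading
recovery checks. Clinical scores are drawn per group and
rejection-sampled until the two-of-three rule reproduces the intended
label, so grouping is internally consistent by construction; only the
clinical scores differ between groups, all other unlinked variables are
group-independent noise.

## Numerical choices and degenerate inputs

* Coordinates are mm, right-handed, z-up after realignment; angles in
  degrees; planar angles wrapped to (-180, 180].
* Projections shorter than 1e-9 of unit length are flagged undefined.
* Eigen-tie threshold 1.05 between leading eigenvalues triggers the PCA
  degeneracy warning; the tie-break keeps eigen order with the
  largest-magnitude component made positive before anatomical sign flips.
* Coincident calcaneus/M2 plantar projections, collinear ground vertices,
  empty footprints, zero-length toe-free regions and out-of-range scores
  all raise errors naming the offending stage.
* Registration falls back with a warning (not an error) when aligned
  contact masks overlap poorly, since a usable average may still exist.
* Binary STL stores float32: coordinates survive a write/read cycle
  exactly when they are float32-representable; the ASCII writer uses
  `%.9g` for the same guarantee.

## Problem sizes used in the checks

The shipped tests and the acceptance script use 300-600 vertices per
synthetic bone, 50 seeded feet for geometry recovery, five trials on a
20 x 56 grid for pressure recovery, 16-patient cohorts for the screen's
structural counts, 100 replicates of n = 200 cohorts for statistical
recovery and around 15,000 null pairs for type-I calibration. These sizes
were chosen so each check exercises the full algorithmic path with
comfortable statistical resolution.

## Known limitations

* Ellipsoid bones and designed footprints validate the algebra, not
  robustness to real segmentation or sensor artefacts.
* The marker-based forefoot masking approximates proprietary platform
  masking; its geometry (anterior-half tangents, pixel-corner hull) is
  documented above but is not a reimplementation of any vendor algorithm.
* The correlation screen is deliberately uncorrected for multiplicity and
  is a hypothesis-generating device; its outputs are effect-size tables,
  not confirmatory inference.
* Only static marker positions in the footprint plane are consumed; no
  multi-segment foot kinematics are computed.
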