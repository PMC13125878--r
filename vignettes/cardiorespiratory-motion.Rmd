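---
title: "Decoupling cardiorespiratory motion of cardiac substructures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoupling cardiorespiratory motion of cardiac substructures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomotion)
```

## The problem

Thoracic radiotherapy deposits dose in and around the heart, and
cardiotoxicity risk is increasingly understood at the level of individual
cardiac substructures — proximal coronary arteries, chambers, great
vessels, valves, and conduction nodes — rather than the whole heart.
Each substructure moves with two superimposed quasi-periodic cycles:
the cardiac cycle (end-diastole ED to end-systole ES) and the
respiratory cycle (end-exhale EE to end-inhale EI), the latter often
with hysteresis (the inhale and exhale limbs of the trajectory do not
coincide). Free-breathing volumetric imaging that is retrospectively
sorted into cardiac-phase-by-respiratory-state bins yields one 3D
volume — and, after contouring, one binary mask per substructure — for
every combination of the two cycles. `cardiomotion` implements the
downstream analysis of such phase-binned masks:

1. retrospective **binning** of surrogate signals (respiratory bellows
   amplitude, cardiac trigger times) into cardiac bins and the four
   respiratory states EE / active exhale (AEx) / active inhale (AIn) / EI;
2. **geometry**: centroids, bounding boxes, geometric valve and
   conduction-node constructions;
3. **decoupled excursion metrics** per substructure: cardiac,
   respiratory, and hysteresis displacement of centroids and
   bounding-box faces, plus directed surface-distance metrics (MDA,
   HD95);
4. **internal organ-at-risk volume (IRV)** margins and masks;
5. **dosimetric impact**: DVH and the near-maximum dose D~0.03cc~ of
   reference vs IRV structures;
6. cohort **statistics** comparing substructure groupings across eight
   motion metrics.

Since no imaging data accompany the methodology, the package ships a
first-class synthetic phantom (`phantom` module) with exactly known
ground-truth motion, against which every downstream stage is validated.

## The decoupling model

Write $d(c, r)$ for the rigid displacement of a substructure at cardiac
phase $c$ and respiratory state $r$. Decoupling rests on averaging one
cycle within fixed states of the other:

* **cardiac motion** is the ED$\to$ES displacement averaged over
  respiratory states,
* **respiratory motion** is the EE$\to$EI displacement averaged over
  cardiac phases,
* **hysteresis** is the AEx$\to$AIn displacement averaged over cardiac
  phases — zero iff the respiratory loop closes.

Displacements are reported as signed RL/AP/SI components (positive
toward patient right / anterior / superior) and a vector magnitude
$\sqrt{RL^2 + AP^2 + SI^2}$. For averaged summaries the **vector is the
mean of per-state norms**, not the norm of the averaged components.
The two disagree whenever per-state directions differ, and the
mean-of-norms convention is the one consistent with cohort tables in
this literature (e.g. a proximal right coronary artery with mean
components $(-5.5, 3.8, -3.6)$ mm but mean vector $8.2$ mm: the norm of
the means is only $7.6$ mm). The invariant `vector >= norm(components)`
is enforced by construction and tested.

Voxelwise agreement between a reference contour $A$ and target $B$ uses
the directed distance $d_a = \min_{b \in B} \lVert a - b \rVert$
evaluated on surface voxels (set voxels with at least one face-adjacent
unset neighbour); MDA is the mean and HD95 the 95th percentile (linear
interpolation between order statistics) of $\{d_a\}$. Distances are
*not* symmetrized; the reference is the end-exhale/end-diastole mask.
Internally the directed distances are computed with an exact separable
squared Euclidean distance transform (anisotropic-spacing-aware,
compiled), and the test suite checks bit-level agreement with an
exhaustive double-loop oracle on small grids.

## IRV margins

For each of the six directions, the internal margin is the **maximal
outward** bounding-box face shift over the relevant phase pairs
(ED$\to$ES per respiratory state for cardiac; EE$\to$EI per cardiac
phase for respiratory), floored at zero — a face moving inward does not
enlarge the at-risk envelope. The cardiorespiratory margin is the
**per-direction sum** of the cardiac and respiratory margins, i.e. the
worst-case envelope of combined excursion. We deliberately do not use a
Boolean union of the two single-motion IRVs: a union can never exceed
either margin in any direction and therefore does not represent
combined motion. Expansion is a Minkowski sum with the axis-aligned box
spanning the margins, voxelized by ceiling (conservative), so the IRV
always contains the reference mask and the containment/monotonicity
properties are provable from the max rule.

Two scope notes. First, margins derived this way encode the extreme
cardiac and respiratory phases only: with non-zero hysteresis the
mid-respiration AEx/AIn positions carry a perpendicular loop offset (up
to half the loop width) that is not part of the ED/ES-EE/EI pairs, so
hysteresis is quantified and reported but *not* folded into the IRV —
consistent with the originating methodology, which found hysteresis
generally below the 5 mm action threshold. Second, planning organ-at-risk
volumes (PRV, adding setup uncertainty) are out of scope.

## Dosimetry

Structure voxel centers are sampled from the dose grid by trilinear
interpolation (exact on linear fields, which makes the analytic tests
sharp, and exact at coincident grid nodes). D~v~ (default
$v = 0.03$ cc) is computed from the descending-sorted voxel doses with
fractional-voxel linear interpolation rather than from a binned DVH, so
it is independent of DVH bin width; structures smaller than $v$ raise an
explicit error rather than silently clipping. Because the hottest-$v$
dose is monotone in the voxel set, an IRV that contains its reference
satisfies $\Delta D_{0.03cc} \ge 0$ exactly; this superset monotonicity
is asserted over randomized phantom/dose configurations.

## Binning rules

Cardiac binning is phase-based: a sample at time $t$ inside the
enclosing RR interval $[t_k, t_{k+1})$ gets bin
$\lfloor N (t - t_k) / (t_{k+1} - t_k) \rfloor$, clamped to $N-1$
(default $N = 10$). Samples outside the trigger range are excluded, not
extrapolated. Respiratory binning is amplitude-based with a 10%/80%/10%
split: sample percentiles (type 7) of the baseline-corrected waveform
define EE ($\le$ 10th) and EI ($\ge$ 90th); the middle 80% is split
into AIn/AEx by the sign of the smoothed slope. Design choices here,
made where the method description was genuinely open:

* **Baseline correction** subtracts a centered moving average with a
  window of two respiratory periods before computing thresholds. This
  reconciles an amplitude-threshold definition with a moving-average
  thresholding strategy, and makes the state assignment robust to slow
  bellows drift (tested under a 0.01 units/s drift).
* **Thresholds are sample percentiles**, not fractions of the amplitude
  range; with stationary waveforms the two agree asymptotically for the
  occupancy contract (EE and EI each own ~10% of samples).
* **Slope** is a central difference of a 0.5 s moving-average smoothed
  copy (the raw derivative is too noisy at realistic noise levels); an
  exactly zero slope tie-breaks to AEx (end of the exhale plateau).
* The respiratory-binning literature is ambiguous between amplitude-
  and phase-based sorting; the amplitude reading matches the
  quantitative 10/80/10 definition and is what is implemented.

## The synthetic phantom: what it emulates, what it does not

The phantom states a world and keeps it fixed:

* **Grid**: 96³ voxels at 1.56 mm isotropic — the reconstructed
  resolution of the targeted free-breathing acquisition, at desk scale.
* **Primitives**: spheres (chambers), constant-radius tubes around a
  polyline (proximal coronary arteries), ellipsoids. Rasterization is
  voxel-center-inside-primitive — the simplest rule that is exactly
  equivariant under lattice translations (no partial volume).
* **Motion**: rigid, cardiac raised-cosine from ED (0) to ES
  (amplitude), respiratory elliptical loop from EE to EI with a
  perpendicular hysteresis offset $\pm (h/2)\sin(\pi\,\text{phase})$ by
  limb, so the loop closes exactly at both extremes and the AEx/AIn
  separation equals $h$. Only the endpoints matter to the downstream
  contracts.
* **Default amplitudes**: cardiac $(-5.5, 3.8, -3.6)$ mm (left /
  anterior / inferior at ES — cohort-mean proximal-RCA magnitudes),
  respiratory $(0, 1, -4)$ mm (SI-dominant, inferior at EI), hysteresis
  drawn uniformly on $[0, 6]$ mm per subject. These sit in the 4–8 mm
  band reported for coronary cardiac motion and the 4–6 mm band for
  respiratory SI motion.
* **Signals**: raised-cosine bellows surrogate with optional linear
  drift and Gaussian noise; trigger times with i.i.d. Gaussian RR
  jitter. Waveform shape defaults are configuration, not a physiologic
  claim — the underlying volunteer waveforms are not described.

It does **not** emulate: image intensities or reconstruction artifacts
(masks are exact), deformation (motion is rigid per substructure),
contour propagation/delineation error, or realistic anatomy. A green
parameter-recovery test therefore establishes that the *analysis
pipeline* is unbiased to within rasterization noise (half a voxel),
not that segmentation-driven uncertainties are controlled.

## Statistics

Groups of substructures are compared per motion type across eight
metrics (RL, AP, SI, vector, mean and max face shift, HD95, MDA) with
the Kruskal–Wallis test (tie-corrected, $\chi^2$ approximation; $H$
defined as 0 for all-tied data) followed by Dunn's mean-rank post-hoc
test, Bonferroni-adjusted over the pairwise comparisons within a
battery. The eight metrics are deliberately *not* corrected across;
instead a grouping/motion-type battery is called overall significant
when at least 4 of the 8 metrics reach $p < 0.05$. Observations are
per-subject, per-substructure summary values (never per-voxel, avoiding
pseudo-replication); with the built-in groupings the subjects are the
replication unit. A simulation helper draws metric tables from a shared
latent displacement so that power and type-I behaviour of the 4-of-8
rule can be studied cheaply; under an identical-distribution null the
overall-significance rate stays below the nominal 0.05 because the
correlated-metrics battery is at worst equivalent to a single test.

## Numerical conventions and edge cases

* Voxel-center coordinate frame everywhere: physical position
  `origin + spacing * (index - 1)`; bounding-box faces are extreme
  voxel *centers* (not outer edges), so centroid and face displacements
  share one frame and rigid lattice shifts move both exactly.
* Isotropic expansion (valves) thresholds the exact Euclidean distance
  transform at the expansion radius — sub-voxel accurate and correct
  under anisotropic spacing, unlike iterated structuring elements.
* HD95 uses `quantile(type = 7)` (linear interpolation between closest
  ranks), stated for bit-reproducibility.
* Exactly-threshold comparisons (a voxel at exactly the expansion
  radius, motion at exactly 5 mm) follow `<=` / strict `>`
  respectively; lattice-aligned geometries can place voxel distances
  exactly on a radius, where floating-point representation decides the
  tie — generic (off-lattice) geometry is tie-free.
* Degenerate inputs raise typed, descriptive errors: empty masks,
  constant waveforms (percentiles coincide), structures smaller than
  the D~v~ volume, spheres of zero radius, oblique NIfTI affines.
* Masks and dose grids are stored as NIfTI-1 (uint8 / float64) with an
  sform affine; on read, any axis-aligned orientation is remapped to
  the package's RL/AP/SI (RAS+) convention and oblique affines are
  rejected rather than resampled.

## Known limitations

* Motion is quantified from two cardiac phases (ED/ES); intermediate
  cardiac phases are not contoured in the targeted workflow and the
  extremes are sufficient for excursion.
* Per-state averaging weights states equally, not by bin occupancy
  (occupancy weighting would couple the motion estimate to the
  breathing pattern of the particular acquisition).
* The IRV "sum of margins" is a worst-case static envelope; it ignores
  the dose-blurring of actual intra-fraction motion and so
  overestimates the delivered near-maximum dose.
* The phantom's rigid motion cannot probe deformation-driven
  differences between centroid and surface-distance metrics; on real
  cohorts those metrics carry independent information.
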