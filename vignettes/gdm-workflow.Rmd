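---
title: "Geometry deformation margins for marker-tracked radiotherapy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry deformation margins for marker-tracked radiotherapy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdmrt)
```

## The problem

Stereotactic arrhythmia radioablation (STAR) delivers a single ablative dose
to a ventricular-tachycardia substrate while the heart moves with both the
cardiac cycle and respiration. Robotic tracking platforms follow a surrogate
marker — typically the tip of an implanted ICD lead — and, with a single
marker, compensate translations only. Tracking the marker is not the same as
tracking the target: the geometric relation between the lead tip and the
ablation target deforms over the breathing cycle. If the clinical target
volume (CTV), delineated on a single expiration breath-hold CT, is expanded
by a generic isotropic margin, parts of the target can drift out of the
treated volume during free-breathing delivery.

`gdmrt` implements a target-definition workflow that measures this
marker–target deformation directly from the planning CT study and converts
it into an anisotropic expansion margin, the *geometry deformation margin*
(GDM).

## The triple registration chain

The planning study consists of a primary expiration breath-hold series and
several motion-sampling secondaries (an inspiration breath-hold and a few
free-breathing scans). Each secondary is registered to the primary three
times:

1. **Spine, 6 DOF** (`register_spine_6d`): rigid alignment on the spine as
   motion-intact anatomy. This removes couch/posture differences and, most
   importantly, body rotations, which single-marker tracking cannot
   compensate. Implementation: mean-squared intensity difference restricted
   to the spine ROI, a coarse exhaustive translation initialization (±12 mm
   at 1.5 mm steps, normalized cross-correlation) for capture range, then a
   multi-resolution (subsampled ROI, two levels) Nelder–Mead refinement of
   all six parameters. Capture bounds: ±40 mm, ±10°. Points that map
   outside the moving volume are excluded from the metric; comparing them
   against a fill value instead would let boundary clipping dominate the
   cost and bias the optimum toward zero shift.
2. **Marker, translation only** (`register_translation_marker`): the marker
   is segmented in both series as the largest 6-connected component above a
   configurable HU threshold (default 1500, separating metal from bone)
   inside the search ROI, and the incremental translation is the difference
   of intensity-weighted centroids. Closed-form, hence exactly reproducible
   and robust to the optimizer-hostile appearance of metal. Rotations are
   frozen at the spine result from here on, mirroring the delivery system.
3. **Reference structure, translation only** (`register_translation_local`):
   the target region itself is hard to discern on CT, so a clearly visible
   intensity heterogeneity inside the heart (clinically, the area around the
   left main coronary artery) serves as an in-organ target surrogate. The
   step maximizes normalized cross-correlation over a dense ±10 mm
   translation search at 0.5 mm steps around the marker alignment, followed
   by per-axis parabolic sub-step refinement. Deterministic by construction:
   no random restarts, so run-to-run variability can only come from ROI
   choice, as in the clinical observer experiments.

The per-series *deformation vector* is the translation of step 3 minus the
translation of step 2 — how far the target surrogate moved relative to the
tracked marker in that breathing phase. Note the error of the spine step
cancels in this difference; what limits accuracy is marker centroiding and
the NCC peak localization.

### Transform convention

Physical coordinates are patient LPS (+x left, +y posterior, +z superior);
this matches the DICOM convention of the clinical systems involved.
A `rigid_transform` maps fixed-frame (primary) points to moving-frame
points, the standard resampling convention: its translation reads as the
displacement of the anatomy from the primary to the secondary series.
Rotations are intrinsic Z-Y-X Euler angles about the ROI centroid. This
orientation of the convention matters: with it, the deformation vector
points where the target surrogate went relative to the marker, which is the
direction the margin must grow, and the union construction below translates
the CTV by the vectors directly.

## From vectors to target volumes

**GDM margin** (`gdm_margin`): for each of the six anatomical directions,
the margin is the largest vector component pointing that way across all
motion-sampling series, clamped at zero. Negative (inward) maxima are never
applied — the method guards against underdose only.

**ITV_GDM** (`expand_anisotropic`): the CTV is expanded by the margin as a
Minkowski sum with the axis-aligned box
\[-R, +L\] × \[-A, +P\] × \[-I, +S\], realized as three separable
one-dimensional dilations. The box kernel is chosen over a rounded
(ellipsoid-octant) kernel because it is the smallest axis-aligned expansion
that provably contains every CTV copy translated by an observed vector —
the property that motivates the method. An `kernel = "ellipsoid"` mode
exists for comparison studies with planning systems that round their
expansions.

Margins are voxelized *outward* (ceiling, after discounting 0.1 voxel).
Outward realization keeps the guarantee under estimation error: a CTV copy
whose true shift rounds to *k* voxels stays covered as long as the margin
estimate is within 0.4 voxel (0.6 mm at the default 1.5 mm pitch) of the
truth, while the small discount prevents sub-voxel registration jitter from
inflating a genuinely zero margin to a full voxel.

**ITV_GDM-SUM** (`itv_gdm_sum`): the alternative construction that unions
the CTV with one translated copy per observed vector (the expiration
identity copy always included). This mimics what merging deformably
registered CTV instances produces. It is never larger than ITV_GDM and
undersamples continuous motion — the reason the maximum-based GDM is the
primary construction and the union is the comparator.

**PTV** (`expand_isotropic`): an isotropic margin by Euclidean distance
transform, default 2 mm, covering registration observer variability and
residual technical uncertainty (3 mm reproduces the original-workflow PTV
convention for comparison runs). The containment chain
CTV ⊆ ITV_GDM-SUM ⊆ ITV_GDM ⊆ PTV_GDM holds by construction and is asserted
voxelwise in the test suite.

## Agreement metrics and observer statistics

Volume agreement uses the DICE coefficient (voxel counting) and the average
Hausdorff distance H-AVE. H-AVE is computed between boundary-voxel centres
(6-connectivity defines the boundary, so results are bit-reproducible) via
an exact anisotropic Euclidean distance transform, and symmetrized as the
mean of the two directed means — the one-line clinical definition is
directed-ambiguous, and the symmetric mean is the convention of the
segmentation-evaluation literature. Surface-mesh distances are out of scope.

The observer-variability machinery reproduces the clinical experiment
design: two observers repeating the full registration chain three times per
patient gives three intra-observer pairs per observer (six measurements per
patient) and nine cross-observer pairs. The package ships the printed DICE
and H-AVE values of the five-patient clinical reference experiment and the
pairwise PTV DICE table of the seven-patient cohort as CSV fixtures
(`clinical_reference_table()`), so every published summary statistic —
per-row mean and sample SD (n−1; reproduces the printed SDs 0.083, 0.036,
0.063), pooled contrasts, grand means, histograms (DICE bin 0.05, H-AVE bin
0.25 mm) — is recomputed rather than quoted. Display rounding follows the
tables: DICE to 2 decimals, H-AVE to 1.

Two fixture quirks are worth recording. The printed table is
typographically inconsistent about which patient columns are absent in the
five-patient rows; the fixture assigns the subgroup uniformly to patients
1, 2, 4, 5, 6, and no computed statistic depends on the assignment. And the
clinical report pairs *t* tests with a 12-versus-60-value comparison that
cannot be paired; `group_test()` therefore provides both a paired mode and
Welch's test, defaulting to Welch when group sizes differ.

The "margin that covers variability" readout (`margin_for_coverage`) is an
inclusive empirical quantile of pooled H-AVE values with an explicit
coverage fraction (default 0.95) rather than a hard-coded 2 mm: the pooled
maximum of the reference values is 3.1 mm, so full coverage and
near-complete coverage answer different questions and the user should see
which one they ask.

## The synthetic phantom

No clinical images ship with the package, so validation runs on a synthetic
respiratory thorax phantom (`phantom_spec`, `generate_series`) with exported
ground truth. It renders, analytically and with a ~2 mm soft edge so
structures move continuously at sub-voxel resolution:

* an elliptical body (soft tissue, 40 HU) with a rigid spine (700 HU)
  carrying periodic vertebral bodies, disc gaps and transverse processes —
  a plain cylinder would leave the longitudinal translation and axial
  rotation unidentifiable, which a real spine never does;
* a heart ellipsoid (300 HU) that breathes;
* a bright marker sphere (3000 HU) and a heterogeneous blob cluster
  (+150 HU over heart) standing in for the coronary-artery reference
  structure, each riding on the heart with its own programmable extra
  offset; optional radial streaks approximate metal artifacts;
* a spherical CTV tied to the reference structure.

The motion model has four independent layers per phase — body (couch-like)
shift, breathing heart shift, marker offset δ_m, reference offset δ_r — so
the quantity the registration chain must recover, δ_r − δ_m, is a
first-class programmed value. The breathing profile is superior–inferior
dominant with the inspiration phase at the amplitude extreme and
deterministic (instructed breath-holds tend to exaggerate the free-breathing
range); free-breathing phases are drawn uniformly within the amplitude under
the study seed.

Default conditions, chosen once as clinically plausible and used by the
validation suite: 96³ voxels at 1.5 mm isotropic, noise SD 20 HU, breathing
amplitude 8 mm, marker offset within ±2 mm, reference offset within
±3.5 mm, body shift within ±3 mm, one inspiration plus three free-breathing
secondaries. Under these conditions the chain recovers each deformation
vector to ~0.2–0.35 mm (well under the one-voxel acceptance bound), and with
the noise turned off to under 0.25 mm.

What the phantom does *not* emulate: beam hardening, scatter, genuine
metal-streak physics, cardiac-cycle deformation beyond a phase offset,
intensity drift between series, or non-rigid organ deformation. Passing the
phantom suite therefore demonstrates that the chain and margin constructions
are correct and self-consistent under realistic geometry, noise and motion
magnitudes — not that registration accuracy on clinical CT will match the
phantom numbers.

## Numerical choices

* Distance transforms: exact squared-Euclidean (Felzenszwalb–Huttenlocher)
  with anisotropic spacing, in compiled code; equality with O(n²)
  brute-force scans is asserted to 10⁻⁹ in the tests.
* Integer voxel shifts round half away from zero (R's `round` is
  half-to-even, which would make tie behaviour platform-lore); stated so
  results are reproducible.
* Isotropic expansion thresholds squared distances with a 10⁻⁹ tolerance so
  voxels exactly at the radius are included (a single voxel dilated by
  2 mm at 1 mm pitch yields the 33-voxel digital ball).
* Masks live on their grid; operations on mismatched grids raise an error
  rather than resampling silently.
* The NCC search declares a reference ROI "not discriminable" when its
  intensity is constant, and fails loudly rather than returning a flat-peak
  arbitrary offset.
* All randomness (phantom rendering, profiles, draws) is governed by a
  single integer seed; reruns are byte-identical including the pipeline's
  JSON report.

## Problem sizes in the shipped suites

The validation suite runs 20 seeded phantoms at the default conditions for
the containment and ground-truth-recovery properties, 50 randomized ≤32³
mask pairs against the metric oracles, and 10 randomized 48³ cases against
the expansion oracles; the acceptance script runs the fixture statistics
plus three seeded phantoms. These sizes were chosen to exercise the
conditions above at desk-scale run times.

## Known limitations

* Rigid transforms only; deformable registration is deliberately out of
  scope (the union construction is the in-package comparator for it).
* Translation-only tracking after the spine step: internal target rotations
  are not compensated, only absorbed into the margin — as in single-marker
  clinical tracking.
* The marker detector assumes the marker is the largest metal object in its
  search ROI.
* DICOM / RT-STRUCT parsing is not provided; images and masks move through
  NRRD or NIfTI-1.
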