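---
title: "Background-referenced quantification of NaF-PET/CT bone-graft uptake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Background-referenced quantification of NaF-PET/CT bone-graft uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftquant)
```

## The problem

After non-instrumented posterolateral lumbar fusion (niPLF), only a minority
of patients achieve bony fusion, and the reference standard for detecting it
— high-resolution CT — shows structural change late. ^18^F-sodium fluoride
(NaF) PET images bone mineralization directly: fluoride exchanges for
hydroxyl ions in hydroxyapatite, so active graft incorporation shows up as
tracer uptake weeks after surgery. Quantifying that uptake reproducibly is
harder than it sounds: graft beds are small, lie against hot cortical bone,
and absolute SUV thresholds transfer poorly between scanners and patients.

`graftquant` implements a background-referenced quantification: the
patient's own paraspinal muscle supplies the reference activity, and the
muscle SUVpeak becomes a patient-specific fixed lower threshold for
segmenting the graft volumes of interest (VOIs). Using the patient as their
own control largely removes between-scanner and between-protocol variance.
The package turns the procedure — originally carried out interactively in
clinical ROI software — into a scripted, config-driven pipeline, and adds a
digital phantom generator plus a cohort simulator so every stage can be
validated against exactly known ground truth.

## The procedure

For each patient with a paired PET (activity concentration, Bq/mL) and CT
(HU) volume:

1. **SUV calibration.** Voxel activity is converted to body-weight SUV,
   `SUV = C / (D(t_scan) / w)`, with `C` in Bq/mL, `w` the body weight in
   grams (1 g/mL tissue density convention), and
   `D(t) = D_0 * 2^(-Δt / T_half)` the injected dose decay-corrected to
   scan start (`T_half` = 110 min for ^18^F). Correcting to scan start is
   the dominant clinical convention; the reference time is a calibration
   field, not a hidden constant.
2. **Fusion.** PET and CT are first aligned purely from header geometry
   (`fuse_from_metadata()`); any residual misalignment is corrected by a
   rigid adjustment supplied in the run config (`refine_rigid()`), the
   scripted equivalent of manually nudging the overlay. PET is then
   resampled onto the CT grid (trilinear), because CT is the
   higher-resolution geometric reference for HU masking.
3. **Muscle background.** A cylindrical VOI (target volume 20 cm^3) is
   placed in the erector spinae, below rib 12 and above the graft region;
   the right VOI is the mirror image of the left. The VOI is restricted to
   CT values in 0–250 HU to exclude fat (≈ −100 HU) and bone (> 250 HU).
   The SUVpeak — the mean over the hottest 1 cm^3 sphere — of each side's
   windowed muscle mask is computed.
4. **Threshold segmentation.** The two muscle SUVpeaks are combined (mean
   by default) into the patient's fixed lower threshold. Within each graft
   VOI, voxels with SUV at or above the threshold are segmented; connected
   components smaller than 1 cm^3 are discarded, suppressing single hot
   voxels and small separated voxel groups.
5. **Uptake totals.** `SUVtotal = SUVmean × segmented volume` (SUV·mL), the
   standard total-lesion-uptake convention; `cSUVtotal` is the same after
   partial volume correction (below). Totals are summed over all insertion
   levels and both sides to one pair of numbers per patient.
6. **Cohort statistics.** Median [min, max] descriptives by fusion status,
   explorative univariate logistic regressions of fusion on each variable
   (odds ratio with Wald 95% CI), and Spearman rank correlations of uptake
   with the 12-month-minus-baseline change of each clinical score (WLK-D,
   VAS-B, VAS-L, TAN, ODI, EQ-5D). Missing values are dropped per test
   (available-case); no multiplicity correction is applied, matching the
   explorative framing — the report instead states how many tests ran.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| HU window | 0–250 | HU | excludes fat (< 0) and bone (> 250) from the muscle reference |
| SUVpeak sphere | 1.0 | mL | the conventional "hottest 1 cm^3" peak definition |
| sphere coverage | 50% | – | a center qualifies only if half the sphere lies in the mask; prevents peaks from slivers |
| threshold rule | mean | – | combination of left/right muscle peaks; `max` and `per_side` available and logged |
| threshold comparison | `>=` | – | inclusive keeps boundary voxels and is deterministic |
| min component | 1.0 | mL | noise-reduction filter; inclusive (`>=`), since voxel quantization makes exact equality a measure-zero event; a strict `>` is available |
| connectivity | 26 | – | conventional for hot-spot PET segmentation; 6 available |
| PVC FWHM | 6 | mm | assumed reconstructed PSF width, typical for the scanner class |
| PVC shell gap / thickness | FWHM / FWHM | mm | background sampled outside the spill-out zone; floored at voxel scale |
| PVC recovery floor | 0.05 | – | below this the correction divides by ≈ 0 and falls back, flagged |

## Partial volume correction

Finite scanner resolution spreads a small hot object's counts outward, so
the measured mean underestimates the true mean, the more the smaller the
object. The correction models the PSF as an isotropic Gaussian of the
configured FWHM. Let `r` be the mean, over the segmented mask, of the
PSF-convolved mask indicator (the fraction of the object's own signal that
stays inside it), and `B` the background SUV estimated from a shell around
the mask (excluding other segmented voxels). Then

```
corrected mean = (observed mean − B · (1 − r)) / r
cSUVtotal      = corrected mean × segmented volume
```

For a homogeneous object on a homogeneous background this inverts the blur
exactly, because blurring is linear: `observed = B + (A − B) · r` solves to
`A`. The corrected mean is floored at the observed mean so a failed
background estimate can never reduce the total, and `r` below 0.05 aborts
the correction (flagged `pvc_unstable`, uncorrected total returned). On
noise-free sphere phantoms (10–40 mm diameter, 6 mm FWHM) the corrected
mean lands within a fraction of a percent of truth while the uncorrected
mean is up to 45% low; the test suite asserts this sweep. The commercial
algorithm used interactively for the original analyses is unpublished, so
equivalence with it cannot be claimed — only recovery performance on
phantoms with known truth.

## The digital phantom

`default_phantom_spec()` builds an 80×60×60 grid at 2 mm spacing (a
160×120×120 mm field): an elliptical body column (40 HU, SUV 0.5), a
central posterior bone column (700 HU, SUV 3), bilateral 20 cm^3 erector
spinae muscle cylinders (50 HU, true SUV 1) cranial to bilateral 4 cm^3
spherical graft hot regions (400 HU, true SUV 5) flanking the bone — the
anatomy the method's VOIs assume, at known truth. PET is produced by
blurring the piecewise-constant true SUV map with the PSF, adding Gaussian
noise with variance proportional to the local mean (a pseudo-Poisson
surrogate; full sinogram-level simulation is out of scope and unnecessary
for stressing thresholding and PVC), and scaling to Bq/mL under a known
calibration (70 kg, 2.2 MBq/kg = 154 MBq, 90-min uptake). A configurable
rigid misalignment can be applied to the PET header to exercise fusion and
resampling. Overlapping regions resolve by declaration order (earlier
wins), and overlaps are reported.

What the phantom deliberately does not emulate: anthropomorphic anatomy,
scanner-specific non-stationary PSFs, PET grids coarser than the CT grid,
attenuation/scatter residuals, or patient motion. Passing phantom tests
therefore demonstrates the correctness of the implementation and the
recovery behavior of the method under its own assumptions — not clinical
accuracy on real scans.

The cohort simulator draws fused status from a binomial (default 4/18),
scores uniformly within the observed ranges of the emulated study
population (12-month score = baseline + a change draw, clipped to
instrument bounds), and summed uptake uniformly in [474, 1766] SUV·mL with
a configurable additive fused/unfused effect (default 0: the null, under
which the logistic CI coverage can be calibrated) and a configurable
rank-level association between uptake and score changes (default 0).

## Numerical choices

- **Geometry.** World coordinates are LPS millimetres (DICOM patient
  space); voxel indices are 0-based in the affine; values sit at voxel
  centers. NIfTI (RAS+) affines are converted on read/write. Euler angles
  are intrinsic z-y-x in degrees about an explicit center — the convention
  any manual adjustment in a config file is interpreted under.
- **Rasterization.** A voxel belongs to a VOI iff its center is inside
  (no partial-voxel weighting) — simple, convergent under refinement, and
  what typical clinical ROI software does. Rasterized cylinder volumes
  converge to `π r² h`; the tests assert < 2% error at 1 mm spacing for a
  20 cm^3 cylinder in generic position. Exactly grid-aligned placements are
  a degenerate (measure-zero) case in which discretization errors can
  cancel non-monotonically, so convergence checks use a generic,
  grid-incommensurate pose.
- **SUVpeak.** Sphere centers are restricted to voxel centers inside the
  mask, the sphere is clipped to the mask, and ties break toward the lowest
  linear index — fully deterministic, and verified against exhaustive
  brute-force search on dozens of random fields.
- **Degenerate inputs.** Empty masks after windowing or filtering are valid
  results (zero volume, zero SUVtotal) with explicit flags, never silent
  zeros; masks smaller than the peak sphere raise a typed error;
  separation in a logistic fit yields a flag instead of a spurious OR.
- **Determinism.** Every stochastic step (phantom noise, cohorts) is
  seeded; identical config + seed reproduces outputs byte-identically, and
  the tests assert it.

## Open design points and how they were fixed

The procedure description this package automates leaves several details to
the operator; each is a config option with a documented default:

- Whether the muscle threshold is the mean of the two sides, their max, or
  per-side is unstated in the source procedure; the default is `mean` (a
  symmetric, robust choice), with `max` and `per_side` selectable and
  echoed into provenance.
- Decay correction to injection vs. scan time is unstated; scan time is the
  default, as the dominant convention, and the calibration object makes the
  choice explicit.
- Cylinder orientation (axial vs. oblique) is an explicit axis in every VOI
  config — there is no hidden default pose beyond axial `(0, 0, 1)`.
- The "best fit" placement of graft VOIs is observer judgment, not an
  algorithm; placements are inputs. An optional helper
  (`center_voi_on_uptake()`) recenters a cylinder on the local uptake
  centroid inside a user box but is never invoked implicitly.

## Problem sizes used in validation

The shipped tests and the acceptance script use: the 80×60×60 phantom at
2 mm spacing; ≥ 50 random fields of up to 16³ voxels for the exhaustive
SUVpeak and connected-component oracles; a 7-point sphere-diameter sweep
(10–40 mm) for PVC recovery; and 100 replicates of 100-patient cohorts for
null calibration of the logistic CI. These sizes were chosen so the full
validation runs in well under a minute on a laptop while every property is
exercised at meaningful scale.

## Known limitations

- Image input is NIfTI; DICOM series must be converted upstream.
- Fusion is header-based plus a configured manual adjustment; there is no
  intensity-based registration optimizer.
- The segmentation quantifies exactly what the VOIs cover; if a VOI misses
  the most distal edge of a graft, its uptake is systematically (slightly)
  underestimated, as in the original manual procedure.
- cSUVtotal is a local-background Gaussian-PSF correction, validated on
  phantoms; it is of the same family as, but not identical to, vendor PVC
  implementations.
- The phantom shares one grid between PET and CT; resampling under
  misalignment is exercised, but PET-grid coarseness is not.
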