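---
title: "Surrogate lymphoma biomarkers from PET maximum-intensity projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate lymphoma biomarkers from PET maximum-intensity projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petmip)
```

## The problem

Two quantitative biomarkers of baseline whole-body FDG-PET carry strong
prognostic information in diffuse large B-cell lymphoma: the **total
metabolic tumor volume** (TMTV, cm³), the volume of all delineated lesions,
and the **dissemination** (Dmax, cm), the largest distance between two
lesions. Both require a full 3D delineation of the whole-body scan, which is
slow and observer-dependent. The idea implemented here is to replace them
with surrogates measured on just two 2D maximum-intensity projections (MIPs)
— the coronal and sagittal views radiologists already use for reading — so
that automated 2D segmentation plus two cheap image measurements stand in
for 3D volumetry:

* **sTMTV** (cm²): per view, the lesion-pixel count of the projected lesion
  mask times the pixel area; the total is the sum of the coronal and
  sagittal components.
* **sDmax** (cm): per view, the lesion mask is reduced to its column-sum
  (x) and row-sum (y) profiles; the distance between the 2% and 98%
  percentile positions of each profile gives robust spans, and the view's
  dissemination is `(x98 − x2) + (y98 − y2)`. The total is again the sum
  over the two views.

The package computes the 3D reference biomarkers, the MIP projections and
surrogates, pluggable 2D lesion segmenters, the agreement statistics between
3D and surrogate quantities, and the downstream survival analysis (risk
stratification, Kaplan–Meier, Cox hazard ratios with bootstrap CIs,
time-dependent AUC) — all testable end to end on synthetic phantoms, since
the clinical trial images the method was developed on are not public.

## Conventions and units

All volumes use a fixed internal axis order: axis 1 left–right, axis 2
anterior–posterior, axis 3 inferior–superior, enforced at the NIfTI reading
boundary by decomposing the header affine (axis-aligned orientations only;
oblique acquisitions are rejected rather than silently resampled). Nothing
is ever resampled: native anisotropic spacing is carried through, so pixel
area is `u·v` mm² even when `u ≠ v`. Internally everything is mm; reported
units are cm³ (TMTV), cm² (sTMTV) and cm (Dmax, sDmax).

The coronal view projects along the anterior–posterior axis and the sagittal
view along the left–right axis, 90° apart; these two views are fixed.
Lesion masks are projected by logical OR along the ray (the maximum of a
binary ray), not by re-thresholding projected intensities.

## Numerical choices

**Percentile convention for sDmax.** The source description does not state
whether profile percentiles are interpolated. We use the discrete
left-continuous quantile of the profile's cumulative mass function:
`q(p)` is the smallest bin index whose cumulative fraction reaches `p`, and
the span is `(q(hi) − q(lo)) × spacing`. This makes degenerate cases exact
(a single occupied bin has span 0, an empty profile 0) and is directly
checkable against a brute-force cumulative scan. It is a documented choice,
not a claim about the original implementation.

**Lesion identity.** Lesions are 26-connected components of the merged 3D
mask (voxels sharing a face, edge or corner), the most inclusive standard
connectivity; Dmax uses component centroids (mean voxel-center position in
mm), not boundary points. Patients with fewer than two lesions have no
defined dissemination: `compute_dmax()` returns 0 with a flag rather than
an error, and the pipeline excludes such patients from survival analysis,
where exclusion belongs.

**Ties and boundaries.** Risk categories use `≤ cutoff` as the low side.
Cox models use Breslow tie handling. The Wilcoxon test enumerates all sign
patterns exactly for n ≤ 12 and otherwise uses the tie-corrected normal
approximation without continuity correction. Bootstrap CIs are seeded
patient-level percentile intervals (default 1000 resamples). The
time-dependent AUC is the IPCW cumulative/dynamic estimator at a fixed
horizon (default 48 months): cases are events on or before the horizon
weighted by `1/G(T−)`, controls are subjects beyond it weighted by
`1/G(τ)`, with `G` a Kaplan–Meier estimate of the censoring distribution;
with no censoring it reduces exactly to the pairwise rank AUC. The exact
estimator variant used originally is not recoverable from the text, so this
standard variant is documented and configurable.

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds a scaled-down whole-body volume (default
64×48×128 voxels at 4 mm): a warm body envelope (trunk column plus head) at
uptake 1, hot physiologic organs — brain, heart and bladder analogues at
uptakes 7, 5 and 8 — that are deliberately *excluded* from the lesion mask,
ellipsoidal lesions at uptakes 4–9 (a voxel belongs to a lesion iff its
center is inside the ellipsoid), and additive Gaussian noise (σ = 0.15)
truncated at zero. Cohorts vary lesion count (1–10) and radius (6–22 mm),
so true TMTV spans more than an order of magnitude. Ground truth carries
the analytic ellipsoid volumes (4/3·π·abc) and the analytic maximum
pairwise center distance.

Simulated outcomes are exponential event times with hazard
`h0·exp(Σβx)` linked to the true biomarkers, with independent uniform
censoring — chosen for closed-form checks (Kaplan–Meier against
`exp(−h0 t)`, Cox recovery of a known hazard ratio).

The phantom is emphatically not a scanner simulation: no point-spread
function, no Poisson reconstruction noise, no scatter, no lesion texture,
no respiratory motion. A green test on phantoms establishes that the
geometry, statistics and plumbing are correct — not that any segmenter
would reach the same accuracy on clinical images.

One phantom property deserves emphasis because it mirrors a real failure
mode of MIPs: a lesion located behind or in front of a hot organ along the
projection ray is invisible to any intensity rule on that view, although
the reference 2D mask (a projection of the 3D mask) still contains it. The
threshold baseline therefore only attains Dice ≥ 0.9 on phantoms whose
lesions are clear of the organ planes; the trainable segmenter can recover
some occluded pixels from context. On clinical images the analogous effect
(bulky disease, physiologic overlap) is a known weakness of 2D surrogates.

## Segmenters

`baseline_segment()` is the deterministic reference point: candidates are
pixels at or above `threshold` (default 0.5) times a robust maximum (the
99.5th intensity percentile), minus pixels inside a configured
physiologic-organ template — the 2D counterpart of the expert step of
removing physiologic uptake. Removal is pixelwise, so a lesion touching an
organ in projection is not discarded with it.

The trainable segmenter is a compact U-Net-style encoder–decoder. No deep
learning framework exists in this R stack, so the network is implemented in
plain vectorized R: three resolution levels (8/16/32 channels), 3×3
convolutions via im2col, max pooling, nearest-neighbour upsampling with
skip concatenation, a sigmoid head, Dice-plus-cross-entropy loss and Adam.
This deliberately replaces the much larger published architecture; what is
preserved is the contract that matters to the pipeline: one model consumes
either view (inputs are fitted to a fixed 48×96 grid by aspect-preserving
resize and pad, and predictions are mapped back), coronal and sagittal MIPs
are independent training samples, and cross-validation folds are split by
patient so that no patient's views straddle train and validation. Inputs
are normalized by clipping at the 99.9th percentile and scaling to [0, 1];
two coordinate channels give the network the spatial context it needs to
suppress location-stereotyped physiologic uptake. Defaults (learning rate
3e-3, 10 epochs, batch size 1) were chosen so that a 60-sample synthetic
cohort trains in about two minutes per fold set on one CPU.

## Agreement and survival analysis

Patientwise segmentation quality pools TP/FP/TN/FN over both views before
forming Dice, sensitivity and specificity (one patientwise value, matching
how single per-patient scores are usually reported; per-view values are kept
alongside, and pooling versus averaging is configurable at the reporting
level). When reference and prediction are both empty the Dice is defined as
1 and flagged.

Between 3D and surrogate biomarkers the package reports Spearman
correlations (tie-aware midranks), median-split concordance (the share of
patients above the median of one biomarker that are also above the median
of the other), and the 3×3 confusion matrix plus accuracy of risk
categories. Risk stratification follows the published rule: low if both
burden and dissemination are at or below their cutoffs, high if both above,
intermediate otherwise. Cutoffs can be supplied (e.g. published values such
as TMTV ≤ 222 cm³ with Dmax ≤ 59 cm), taken as sample medians, or chosen by
maximizing the two-group log-rank statistic over the inner deciles — the
derivation of the published cutoffs is not stated, so all three documented
options are offered.

## Design decisions that were genuinely open

* **NIfTI I/O** is a minimal internal reader/writer (3D payloads, scalar
  datatypes, slope/intercept scaling, axis-aligned sform/qform) because no
  NIfTI package is available in the target R stack; round-trips are
  bit-exact for masks and 1e-6-relative for float32 intensities, and the
  reader is cross-checked against an independent Python reader in the
  tests.
* **Cox fitting and log-rank statistics** are delegated to the `survival`
  package; the package's own tests verify the fitted coefficient against an
  independent grid search of the Breslow partial likelihood. Kaplan–Meier
  and the IPCW AUC are implemented directly (no time-dependent ROC package
  is available here) and KM is cross-checked against `survival::survfit`.
* **Masks are binarized at 0.5** on reading, with a warning for \{0, 255\}
  encodings, because that dialect is common in the wild; genuinely
  non-binary masks are an error.
* **Survival simulation censoring**: `censoring_rate = 0` means no
  censoring at all (every record an event), so the exponential closed form
  is exact; the uniform censoring window is bounded by the horizon.

## Known limitations

Oblique or 4D NIfTI inputs are rejected. The phantom's organ set is three
fixed analogues; real physiologic uptake is far more varied. The trainable
segmenter is CPU-sized and should not be expected to match a full-scale
model on clinical data. Multivariate Cox models with clinical covariates,
competing risks, SUV conversion and DICOM ingestion are out of scope.
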