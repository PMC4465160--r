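---
title: "CT-to-CBCT rigid setup correction and rectal distension: models and methods"
author: "cbctreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT-to-CBCT rigid setup correction and rectal distension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cbctreg)
```

## The problem

In image-guided radiotherapy (IGRT) of prostate cancer, a cone-beam CT (CBCT)
is acquired on the treatment machine before each fraction and registered to
the planning CT to verify and correct the target position. To first order the
prostate behaves as a rigid body, so a 6-DOF rigid registration (RR) — three
rotations, three translations — captures both the day-to-day setup error of
the bony anatomy and the independent motion of the gland, which is pushed
around mainly by rectal filling. `cbctreg` implements three automatic
intensity-based strategies and the evaluation and quality-assurance machinery
around them:

* **global RR** — whole gray-value images, restricted to patient body masks;
* **bony RR** — images clamped from below at a bone threshold so only the
  pelvic bone edges drive the metric; estimates the setup error;
* **local RR** — the bony result refined with the metric restricted, on the CT
  side, to the clinical target volume (CTV, the whole prostate gland) expanded
  by a margin of 1–20 mm.

Registered transforms are applied to the planning contours to produce
automatic CBCT contours, which are compared against reference CBCT contours
by the Dice coefficient and a bidirectional surface distance.

## Similarity metric

CBCT intensities are not calibrated to Hounsfield units, but they are related
to CT intensities approximately by a linear map. The metric is therefore the
mean-subtracted normalized cross-correlation

$$\mathrm{NCC} = \frac{\sum_i (f_i - \bar f)(m_i - \bar m)}
{\sqrt{\sum_i (f_i - \bar f)^2 \sum_i (m_i - \bar m)^2}},$$

which is invariant to positive linear intensity maps of either image. The
sample set runs over fixed-grid (CBCT) voxels where the fixed mask is 1, the
mapped point falls inside the moving (CT) volume, and the nearest-sampled
moving mask is 1 — i.e. the intersection of both masks, with moving values
linearly interpolated. Fewer than 100 samples is treated as an error
(degenerate mask intersection); a zero-variance channel likewise.

The fixed image is the CBCT and the moving image the CT, so the recovered
transform maps CBCT physical points into CT space and the planning contours
are propagated onto the CBCT grid by nearest-neighbor *pull-back* through the
very same transform — no inversion is needed at propagation time, and the
propagated mask stays strictly binary.

## Optimizer and multi-resolution scheme

The optimizer is a deterministic relaxed gradient descent in a scaled
parameter space where 1 radian of rotation is commensurate with 50 mm of
translation. Per iteration the parameters move one learning-factor step along
the normalized negative metric gradient. The gradient is computed
analytically — moving-image gradients (central differences between
neighboring voxels) chained through the rigid-transform Jacobian, the way
ITK-style registration frameworks differentiate NCC; the sample set is
treated as fixed under the differentiation. The alternative, finite
differences *of the metric* (available as `reg_config(gradient = "fd")`),
differentiates the noise roughness of the unsmoothed finest pyramid level
rather than its smooth shape: the spurious gradient reversals that produces
relax the step prematurely and leave the shallow rotation axes (rotation
about the lateral axis, the one limited by 3 mm CT slices) under-converged
by ~0.5 degrees. The two estimators are cross-checked on smooth volumes in
the test suite. The learning factor starts at 0.5 and is
multiplied by 0.7 every time the gradient reverses direction (negative dot
product with its predecessor); optimization stops when the factor drops below
0.1, the gradient norm falls below 1e-5, or 500 iterations are reached.
Because a fixed-step descent can end on an oscillation, the best-metric
iterate is returned, which guarantees the reported transform is never worse
than its initialization.

Registration runs over a 3-level pyramid: shrink factors (4, 2, 1) with
Gaussian pre-smoothing of (4, 2, 0) mm; masks are subsampled without
smoothing so they stay binary. Each level seeds the next. Small CTV margins
can leave a coarse level with fewer than 100 metric samples; such levels are
skipped and the transform falls through to the next finer level.

Two choices the source method leaves open were fixed here and are worth
knowing: the rotation composition order is Rz·Ry·Rx about an explicit center
(the CTV centroid for local RR, the fixed-image center otherwise — the center
strongly affects rotation/translation coupling), and the "projected gradient"
tolerance is interpreted as the norm of the gradient in scaled parameter
space.

## Pre-processing

Five steps precede registration:

1. **Isocenter offset** — the planning CT origin is shifted so the plan
   isocenter coincides with the machine isocenter at (0,0,0).
2. **Body masks** — threshold (defaults −300 HU / −400 au, configurable;
   the source values are unstated), largest 6-connected component,
   morphological closing with a 3-voxel ball, slice-wise hole fill. This
   removes the treatment table and exterior artifacts from the metric.
3. **Bone thresholding** (bony RR only) — clamp-from-below at 150 HU (CT) /
   −140 au (CBCT). The clamp realization flattens everything below threshold
   to a constant, keeping the bone edges as the only gradient; the
   replacement value below threshold is a design choice, as the source
   specifies only the threshold.
4. **Replace gas by tissue** (global and local RR only, switchable) — clamp
   below −150 HU (CT) / −500 au (CBCT). This removes the gas/tissue contrast
   in the rectum that can capture the local metric. Bony inputs are never
   filtered; the bone clamp already removes gas contrast.
5. **CTV margin expansion** (local RR only) — the CT-side mask becomes the
   CTV expanded by 1, 3, 5, 8, 10, 12, 15 or 20 mm. Expansion uses an exact
   Euclidean distance transform in physical millimetres, not voxel dilation,
   because the grids are anisotropic (3 mm CT slices).

## Evaluation

* **Dice**: $2|A\cap B| / (|A| + |B|)$ on a shared grid.
* **BLD/BD**: at each reference surface point the bidirectional local
  distance is the maximum of its forward nearest-distance to the target
  surface and the largest distance of the target points associated back to
  it; BD is the mean BLD over the reference contour. Surfaces are voxel
  face-boundary centers (6-connectivity, volume border counts as background)
  — a resolution-dependent convention, pinned by an all-pairs brute-force
  oracle in the tests. The reference is always the manual (truth) contour, so
  BD is deliberately asymmetric.
* **Failure criterion**: a registration is unsuccessful when its Dice falls
  strictly below 95% of the no-registration Dice (planning CTV simply
  carried over after the isocenter offset). The alternate published reading
  — also below an absolute 0.95 — is available as a `cap` argument.
* **Manual-contour RR** provides the per-pair upper bound any intensity-based
  method could reach, by registering the (1-voxel-smoothed) binary contours
  themselves.

## Rectal distension and failure prediction

Local RR fails mostly when rectal filling changed between scans near the
prostate. The distension statistic uses only the planning contours and the
two gray-value images after bony alignment:

$$F = \left| (\bar I_{CBCT,r} - \bar I_{CBCT,p}) - (\bar I_{CT,r} - \bar I_{CT,p}) \right|$$

where the $r$ means are over $R_{partial}$ — the intersection of the
margin-expanded CTV with the CT rectum contour — and the $p$ means over the
prostate. Subtracting the prostate means cancels any constant intensity shift
between CBCT acquisitions (asserted exactly in the tests); a pure CBCT *gain*
is not cancelled, a documented limitation. CBCT means are computed by mapping
the masked CT voxel centers through the bony transform and sampling the CBCT
linearly (pull-back), which avoids mask-resampling bias; resampling the CBCT
once to the CT grid agrees within interpolation tolerance. F is computed on
*unfiltered* images — the gas filter would erase the signal F measures.
Failure is predicted when F strictly exceeds a cutoff, default 104.4, the
midpoint of the published bounds F1 = 61.2 (below which every observed
registration succeeded) and F2 = 147.6 (above which every observed failure
lay).

## The phantom: what it emulates, and what it does not

Because the patient dataset is available only on request, every quantitative
check in this package runs on a constructive-solid pelvis phantom with known
ground truth:

* grids: CT 160×160×60 at 1×1×3 mm, CBCT 160×160×168 at 1 mm isotropic
  (tests use a 2× coarser grid over the same field of view to stay inside
  their time budget; the transform-recovery acceptance suite runs at full
  resolution);
* anatomy: body ellipsoid, two iliac ellipsoids and a sacrum block (700 HU),
  prostate ellipsoid (40 HU) abutting a posterior rectal tube (wall at
  tissue 30 HU), bladder ellipsoid (10 HU) superior-anterior. The bladder is
  placed with an ~8 mm gap to the prostate surface, so the 8-mm local mask
  contains rectum but no bladder edge — margins of 10 mm and above start to
  include the bone-anchored bladder boundary, which degrades large-margin
  accuracy the way the published margin sweep does;
* CBCT model: au = 0.9·HU − 20, Gaussian noise σ = 10 au, optional ±150 au
  streak lines through gas pockets (off by default). No scatter, beam
  hardening or cone-beam reconstruction physics;
* motion: a 6-DOF setup transform applied to the whole anatomy, plus an
  independent prostate translation. The rectal tube axis follows the
  prostate offset inside a ±30 mm peri-prostatic window (10 mm taper), so
  the abutting anterior wall moves with the gland; prostate rotation
  relative to the bones is not modeled (the gland is treated as rigid);
* distension: the CBCT rectum radius is the CT radius times a distension
  factor ≥ 1; a coaxial lumen filling the given fraction of the rectal
  cross-section within the peri-prostatic window is set to gas (−1000 HU
  equivalent), on either or both scans. Organ priority at rasterization is
  bone > prostate > bladder > gas > rectal wall, so distended rectums wrap
  around, never overwrite, the gland;
* determinism: one RNG stream per pair seeded from the spec; cohorts derive
  child seeds from the cohort seed.

Truth structure masks on the CBCT grid are rasterized analytically from the
transformed geometry, not resampled from CT masks, and stand in for the
manual CBCT contours during evaluation.

A green test on this phantom establishes that the algorithms do what they
claim under a controlled, noise-limited world with exactly known truth; it
does not establish clinical accuracy on patient CBCTs, whose texture, organ
deformation and reconstruction artifacts the phantom deliberately omits.

Default levels worth recording: noise σ = 10 au is of the order of the
soft-tissue contrasts (prostate–tissue 10 HU), making the local registration
realistically noise-limited; setup errors up to ±8 mm / ±3°, prostate
offsets up to 6 mm, distension factors up to ~1.7 with gas fractions up to
0.9 span the protocol-compliant to severely distended range.

## Numerical choices and degenerate inputs

* Axis-aligned grids only; a voxel's physical position is its center;
  0-based indices. Oblique (direction-cosine) headers are rejected at read
  time rather than silently mishandled.
* Outside-support fill values: modality air (−1000 HU CT, −500 au CBCT),
  masks fill 0; metric samples outside the moving support are excluded, not
  filled.
* Masks resample nearest-neighbor (binarity), images linearly.
* The local RR intersects the CBCT body mask with the pulled-back CT ROI
  dilated by 15 mm — far beyond the optimizer's travel from its bony
  initialization — which leaves the metric's sample set unchanged while
  skipping most of the fixed-grid scan.
* Empty masks error ("empty structure"); Dice of two empty masks is
  undefined and errors; an empty R_partial makes F undefined for that pair.
* Summary SD uses the sample (n−1) convention; a single-pair SD is reported
  as 0 with a warning. Reports round Dice to 3 decimals and millimetres to 2.
* BLD ties (several targets equidistant) associate to the lowest reference
  index, deterministically.

## Known limitations

* The CBCT intensity model is linear with additive Gaussian noise; real CBCT
  artifacts (streaks are a crude option here) can defeat both the
  registration and F in ways the phantom underestimates.
* F mixes CT and CBCT intensity units by subtraction, inheriting the linear
  intensity assumption; a gain drift between CBCT acquisitions changes F.
* BD is computed between voxelized surfaces, so its absolute value depends
  on grid resolution; comparisons are only meaningful on a fixed grid.
* The failure criterion compares against the no-registration Dice, so with
  tiny setup errors an accurate registration can still be labelled a
  "failure" — a property of the criterion, reproduced faithfully.
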