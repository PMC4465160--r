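# cbctreg — CT-to-CBCT rigid setup correction for prostate radiotherapy

`cbctreg` is an R toolkit for automatic prostate setup correction in
image-guided radiotherapy: it rigidly registers a treatment cone-beam CT
(CBCT) to the planning CT, propagates the planning contours, evaluates the
result, and scores rectal distension to predict when the registration should
not be trusted. Its audience is medical-physics and image-analysis
researchers who want a self-contained, fully testable implementation of this
pipeline without patient data: a built-in digital pelvis phantom generates
paired CT/CBCT scans with exactly known ground truth.

## What it computes

Three masked rigid (6-DOF) registration strategies, all driven by the
mean-subtracted normalized cross-correlation

    NCC = Σ(f − f̄)(m − m̄) / sqrt(Σ(f − f̄)² · Σ(m − m̄)²)

over the intersection of a CBCT-side and a CT-side mask (NCC is invariant to
the linear intensity map relating uncalibrated CBCT values to Hounsfield
units), optimized by relaxed gradient descent (step 0.5, relaxation 0.7 on
gradient reversal, step tolerance 0.1, gradient tolerance 1e-5, ≤ 500
iterations) over a 3-level multi-resolution pyramid:

* **global** — body masks on both sides;
* **bony** — both images clamped from below at the bone threshold
  (150 HU CT / −140 au CBCT), so bone edges alone drive the alignment;
* **local** — bony refinement with the CT mask replaced by the prostate CTV
  expanded by a 1–20 mm margin (exact Euclidean expansion in mm).

A replace-gas-by-tissue filter (clamp below −150 HU / −500 au) can be
applied to the global and local inputs. Propagated contours are scored by
the Dice coefficient `2|A∩B|/(|A|+|B|)`, a bidirectional surface distance
(BD, the mean of per-point bidirectional local distances), and a failure
criterion (Dice after < 95% of the Dice without registration). Rectal
distension is quantified, from planning contours and gray values only, as

    F = |(Ī_CBCT,r − Ī_CBCT,p) − (Ī_CT,r − Ī_CT,p)|

with the `r` means over R_partial (margin-expanded CTV ∩ CT rectum) and the
`p` means over the prostate, CBCT values sampled after bony alignment;
failure is predicted when F exceeds a cutoff (default 104.4 = (61.2+147.6)/2).

## Worked example

```r
library(cbctreg)

# a phantom pair: 5 mm setup error plus an independent 4 mm prostate shift,
# moderate rectal distension with gas in the treatment scan
spec <- phantom_spec(setup_transform = rigid_transform(c(0, 0, 0.01), c(5, -2, 0)),
                     prostate_offset = c(0, -4, 0),
                     distension_factor = 1.4, gas_fraction = 0.7, seed = 42)
pair <- generate_pair(spec)

bony  <- register_bony(pair$ct, pair$cbct)
local <- register_local(pair$ct, pair$cbct, pair$ct_structs$ctv,
                        margin_mm = 8, bony_result = bony)

prop  <- propagate_contour(pair$ct_structs$ctv, local$transform, grid_of(pair$cbct))
d0    <- dice_noreg(pair$ct_structs$ctv, pair$cbct_structs_truth$ctv)
d8    <- dice(prop, pair$cbct_structs_truth$ctv)
rp    <- compute_rpartial(pair$ct_structs$rectum, pair$ct_structs$ctv, 8)
f     <- compute_F(pair$ct, pair$cbct, bony, pair$ct_structs$ctv, rp)

cat(sprintf("Dice without RR %.3f, after 8-mm local RR %.3f, failed: %s\n",
            d0, d8, is_failure(d8, d0)))
print(f)
```

```
Dice without RR 0.677, after 8-mm local RR 0.945, failed: FALSE
DistensionResult: F = 889.3 (cutoff 104.4) -> failure predicted; R_partial 700 voxels
```

The local registration recovers the prostate despite the setup error and the
independent gland shift (Dice 0.677 → 0.945). The severe injected gas change
drives F far above the cutoff, so this pair would be flagged for visual
review before trusting a local registration — on this pair the registration
still succeeded, i.e. the flag is a conservative pre-treatment warning.

Cohort-level studies (`make_cohort()` + `run_experiment()`) emit per-pair
CSVs, per-method summary tables (Dice/BD median and SD, failure counts) and
an F-sorted success/failure report. A thin command-line front end lives at
`inst/cli/cbctreg.R` (`simulate`, `register`, `distension`, `run`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates a 6-pair phantom cohort spanning empty-rectum to
severely-distended states, runs the global, bony and 8-mm local strategies
with and without the gas filter, evaluates Dice/BD/failures and F for every
pair, prints the per-method summary and writes the cohort tables next to the
output file.
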