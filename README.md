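# petmoco

Head motion during brain PET acquisitions blurs the reconstructed image and
biases regional uptake values. Frame-based, data-driven motion correction
(ddMC) estimates a rigid transform for every short time frame of the scan
and realigns the frames to a common reference before integration; clinical
workflows then need to decide *for which scans* that correction actually
matters. `petmoco` implements the full evaluation methodology for that
question in R, for physicists and method developers who want to study
motion-correction behaviour quantitatively without patient data:

* a procedural 3-D brain phantom with the standard regions of interest
  (whole brain, cerebellum, frontal/parietal/temporal/occipital cortex,
  striatum, thalamus, hippocampus, grey and white matter), two tracer
  contrast regimes (high-uptake FDG-like, low-uptake MET-like), and
  Poisson counting noise at a constant expected count per frame;
* rigid-body transform algebra, trilinear/cubic volumetric resampling and
  a seeded motion-trajectory generator (static, gradual drift, one-time
  step, jitter, composites);
* `estimate_motion()`, the package's core estimator: every frame is
  rigidly registered to a reference frame by maximising the zero-normalised
  cross-correlation over 6 parameters (Nelder–Mead on a two-level
  resolution pyramid, temporal warm starts);
* image-space motion correction and duration-weighted integration into the
  corrected/uncorrected static pair (ddMC / noMC);
* motion summarisation: two virtual probe points 70 mm anterior and
  posterior of the brain centre are moved through every frame transform;
  the larger of the two median absolute displacements categorises the scan
  (low < 1 mm, medium 1–2 mm, high > 2 mm), and the cumulative
  displacement-time histogram (cDTH) shows the fraction of scan time spent
  at or below each displacement;
* image-quality evaluation: a brain mask from the 16-mm-smoothed reference
  frame thresholded at 30% of its smoothed maximum, per-frame normalized
  cross-correlation (XC, 3 mm smoothing) against the reference, and its
  median over frames;
* ROI statistics: relative signal differences
  `(ddMC − noMC) / ddMC × 100%`, median/IQR group summaries, exact
  Mann–Whitney U tests with Bonferroni correction, and the ≤ 1 mm
  registration quality-control criterion.

## The model in brief

A scan is a frame series `I_f` on a common RAS grid. Subject motion is a
per-frame rigid transform `T_f` (extrinsic rotations `Rz·Ry·Rx` in degrees,
translations in mm, about the brain centre) mapping reference-space
coordinates into frame-f space; the reference frame has `T_ref = I`.
Simulation pushes the phantom activity `A` forward
(`I_f = A ∘ T_f⁻¹`, PSF-blurred, Poisson-sampled at 5·10⁵ expected
events/frame); correction pulls each frame back
(`Î_f(x) = I_f(T̂_f(x))`). The estimator finds
`T̂_f = argmax_T XC(I_f ∘ T, I_ref)` with
`XC(a,b) = Σ(a−ā)(b−b̄) / √(Σ(a−ā)² Σ(b−b̄)²)`.

## Worked example

```r
library(petmoco)
cfg <- run_config(seed = 42, pattern = "drift", translation = c(0, 5, 0),
                  rotation = c(2, 0, 0), n_frames = 10)
res <- run_pipeline(cfg)     # add out_dir = "report" to write the bundle
print(res)
```

```
Motion-evaluation pipeline result
Motion category: high (deciding median 2.82 mm, posterior probe)
  median XC: noMC 0.7831, ddMC 0.9061
  whole-brain relative difference 0.726%
```

The scan drifts to 5 mm / 2° by scan end, so the estimated median probe
displacement (2.82 mm) lands in the high-motion category. Correction lifts
the median XC of the 30-s frames from 0.78 to 0.91 — frames agree much
better with the reference after realignment — and the whole-brain mean
signal is 0.73% higher with correction than without, the blur the
uncorrected integration loses. Per-ROI differences are in
`res$roi_rel_diff` (cortical regions mostly positive, white matter
negative, as blur moves counts from the bright cortical ribbon into
white matter):

```r
print(round(res$roi_rel_diff, 3))
#>     FC     PC     TC     OC    CTX    CER    STR    THA    HIP     GM     WM     WB
#> -2.286  1.121  1.174 13.361 -0.551  2.568  2.187  2.350  1.925  2.366 -1.514  0.726
```

Individual stages are available as plain functions (`make_phantom`,
`make_trajectory`, `simulate_frames`, `estimate_motion`, `correct_series`,
`probe_displacements`, `categorize_motion`, `cdth`, `make_brain_mask`,
`xc_series`, `roi_means`, `mann_whitney_u`, …), with NIfTI/TSV/JSON
readers and writers for real data. `summary()`, `coef()` and `plot()`
methods on the estimated trajectory give the motion report directly.

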