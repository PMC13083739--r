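---
title: "Evaluating data-driven motion correction for brain PET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating data-driven motion correction for brain PET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`petmoco` quantifies how rigid head motion degrades dynamic brain-PET data
and how much frame-based motion correction recovers. This vignette explains
the models behind each stage, the parameters that matter, and the design
choices made where the design was genuinely open. Everything stated here is
either a definition or a property the package's test suite computes itself;
no patient data are involved anywhere.

## The motion model

Head motion within a scan is modelled as a per-frame rigid transform: three
rotations (degrees, extrinsic, composed `Rz · Ry · Rx` about the world
axes) and three translations (mm), about an explicit rotation centre. The
centre defaults to the brain centre, because the motion summary is defined
relative to it. Transforms map *reference-space* coordinates into
*frame space*; the reference frame's transform is the identity by
construction, which makes "no motion" and "the reference" coincide
naturally. With that convention the simulator pushes activity forward
(frame `f` shows the anatomy moved by `T_f`), and correction is the
pull-back: frame `f` resampled through `T_f` lands back in reference
space. Composition, inversion and Euler-angle recovery stay well
conditioned because head motions of interest are a few degrees at most,
far from gimbal lock.

## The phantom and what it does and does not emulate

`make_phantom()` builds procedural geometry: an ellipsoidal cerebrum
(semi-axes 55 × 70 × 50 mm) with a folded cortical shell whose thickness is
modulated by seeded angular harmonics, a cerebellum, paired striatum,
thalamus and hippocampus, ventricle-like voids, and white matter filling
the rest. The cortical shell is split into frontal, parietal, temporal and
occipital sectors by anatomical half-planes, and composite regions (grey
matter, white matter, whole brain) are unions of base labels. The default
grid is 48³ voxels at 4 mm (192 mm field of view).

Two contrast regimes are provided. `fdg_like` uses grey:white activity
4.0 : 1.5 (ratio ≈ 2.7, typical of FDG). `met_like` compresses the
contrast to 1.3 : 0.9 and lowers overall uptake so that the global mean is
roughly 0.4 of the FDG-like phantom; published work motivates "lower
accumulating" but prints no ratio, so the 0.5 ceiling asserted in the
tests is a package choice. Because frames are scaled to a constant
expected count, it is the *contrast compression* — grey matter's smaller
share of total activity — that gives the MET-like regime its lower
per-voxel SNR, not the global scaling.

A seeded smooth texture (~12% modulation at ~10 mm scale) multiplies the
activity. It serves two purposes: real anatomy is left-right asymmetric,
and without asymmetric structure rotations about the anterior axis are
nearly unidentifiable to any intensity-based registration; and piecewise
constant images are unrealistically easy to register.

What the phantom does **not** emulate: attenuation, scatter, randoms,
decay, kinetics (the tracer distribution is static within a scan, the same
assumption frame-based correction itself makes), intra-frame motion, and
tomographic reconstruction — noise is per-voxel Poisson on the expectation
image rather than propagated through a projector. Tests passing on this
phantom therefore demonstrate correctness of the *evaluation machinery*
and the direction of motion-blur effects, not clinical effect sizes.

## Simulation

`simulate_frames()` moves the activity by each frame's transform,
optionally blurs it with an isotropic Gaussian PSF (default 5 mm FWHM,
typical of clinical brain PET), scales it so the expected total equals
`counts_per_frame` (default 5·10⁵ events, the constant-count framing used
for data-driven motion estimation), and draws per-voxel Poisson counts.
Frame durations are constant by default; the published acquisitions have
constant counts and *variable* durations, but timing enters the evaluated
metrics only through duration weights, which are exercised separately with
non-uniform timing tables. A `noise = "none"` mode returns expectations
directly and is the basis of every zero-noise oracle in the test suite.

## Motion estimation

`estimate_motion()` registers every frame to the reference frame by
maximising the zero-normalised (Pearson-form) cross-correlation — the same
statistic the evaluation uses — over the six rigid parameters with
Nelder–Mead, on a two-level pyramid (2× block-mean downsampled, then
native), warm-starting each frame from its temporal neighbour's estimate
walking outward from the reference. All-zero frames are returned as
identity, flagged unreliable, with a warning. The estimator never modifies
its input.

Two numerical choices deserve explanation:

* **Cubic interpolation inside the objective.** Linear interpolation
  attenuates high spatial frequencies by an amount that depends on the
  sub-voxel offset. Inside a similarity objective this is not just blur:
  for a small rotation, "do nothing" keeps near-axis texture perfectly
  correlated while "rotate back" decorrelates it, so the optimum is
  dragged toward zero motion. Keys cubic convolution (a = −0.5) keeps
  enough of the spectrum to remove most of that bias; the objective also
  accumulates its sums on a strided lattice fixed in reference space
  (stride 2 when ≥ ~10⁴ samples remain), which costs resolution but can
  introduce no transform-dependent bias.
* **Pre-smoothing, default 10 mm FWHM.** Heavier smoothing both stabilises
  low-count frames and suppresses the residual interpolation-aliasing
  bias; on the default phantom, probe-point recovery error drops roughly
  threefold between 6 mm and 10 mm pre-smoothing at zero noise. Values
  below ~8 mm trade bias for sharpness and are configurable.

Under the study conditions (48³ × 4 mm grid, 5·10⁵ counts/frame), the test
suite verifies recovery of zero-noise trajectories up to 6 mm probe
displacement within 0.3 mm, and a median probe error under 0.5 mm for a
Poisson-noise drift series.

## Correction and integration

`correct_series()` resamples frame `f` through `T_f` (trilinear; no
iterative deblurring), leaving the reference frame untouched;
`integrate_series()` forms the duration-weighted voxelwise mean — the
image-space surrogate for a static reconstruction. This inter-frame,
image-space correction is an explicit stand-in for correction inside a
list-mode reconstruction: it cannot address intra-frame motion, and each
correction costs one interpolation. For that reason the tests judge
"recovered anatomy" by mean deviation and correlation (and, end to end, by
the masked XC metric below) rather than by pointwise maxima, which are
dominated by steep edges under double interpolation.

## Motion summary: probes, categories, cDTH

Two virtual probe points sit 70 mm anterior and 70 mm posterior of the
brain centre along +y/−y (RAS). Per frame, each probe's displacement is
the Euclidean distance between its transform-mapped and reference
positions; a pure rotation θ about an axis through the centre displaces a
probe at perpendicular distance d by exactly `2 d sin(θ/2)`, which the
tests use to recover d = 70 mm to < 0.01 mm.

Categorisation takes the per-probe *median* absolute displacement over
frames, unweighted by duration (motion-estimation frames carry
near-constant counts, not constant durations; a duration-weighted variant
sits behind a flag), and the larger of the two medians decides: low below
1 mm, high above 2 mm, medium in the closed interval [1, 2] mm. The
boundary values themselves are assigned to medium — with strict outer
inequalities printed on both sides, the closed middle interval is the only
consistent reading.

The cumulative displacement-time histogram reports, for each threshold
(0.1 mm bins, non-strict ≤), the fraction of total scan *time* spent at or
below that displacement, per probe. It is normalised, monotone, invariant
to frame order, and duration-weighted; for equal-duration frames its value
at the deciding median is at least 0.5 (median-quantile duality, exact on
odd frame counts). Because the median ignores *when* motion happened, a
brief large excursion and a sustained drift can share a category while
having very different cDTHs — which is precisely the argument for
reporting the cDTH alongside the category.

## Image-quality evaluation: mask and XC

The brain mask smooths the reference frame with a 16 mm FWHM Gaussian and
keeps voxels at or above 30% of the *smoothed* volume's maximum (the
smoothed maximum, not the raw one — thresholding is applied to the
filtered data). XC smooths both volumes with 3 mm FWHM and computes the
Pearson-form correlation over mask voxels; the zero-mean form is the only
one that guarantees the 1 / −1 anchors under additive background offsets.
Both volumes are smoothed globally and the sums then restricted to the
mask. Gaussian sizes are FWHM (σ = FWHM/2.3548), kernels truncated at 4σ
and renormalised at volume edges. The per-series summary is the median XC
with the reference frame excluded (its value is 1 by construction).

## ROI statistics

Relative signal difference per ROI is `(ddMC − noMC)/ddMC × 100%`;
positive means correction recovered signal. Group summaries use medians
and quartiles with linear interpolation between order statistics (quantile
type 7; the convention is a package choice). The Mann–Whitney U test uses
midranks; for combined samples up to 20 the two-sided p-value is exact —
the U distribution enumerated over all label assignments, with
p = min(1, 2·min(lower tail, upper tail)) — and larger samples use the
tie-corrected normal approximation with continuity correction. Doubling
the minimal tail is one of several exact-test conventions; it is the one
implemented and tested against full permutation enumeration. Bonferroni
correction defaults to a family of 11 ROI tests. Registration QC passes
when two displacement vectors differ by at most 1 mm in Euclidean norm,
boundary inclusive.

## Problem sizes and reproducibility

The packaged defaults are the study conditions: 48³ voxels at 4 mm,
5·10⁵ counts/frame, 30 s evaluation frames, 70 mm probes, 16 mm/30%/3 mm
mask and XC parameters, 1/2 mm category boundaries, α = 0.05 with m = 11.
The test suite and examples run shorter series (4–10 frames) and a 36³ ×
5 mm phantom where the full scan length adds nothing to the property being
checked; the end-to-end pipeline example uses 10 × 30 s frames. All
randomness flows through explicit seeds — phantom folding and texture,
trajectory jitter, and Poisson draws are independently seeded — so every
figure and table the pipeline emits is byte-reproducible from its
configuration.

## Known limitations

* Image-space correction cannot model intra-frame blur or count-weighted
  event realignment; effect sizes on the phantom are larger than the
  sub-percent differences typical of patient data, because the phantom's
  cortical ribbon is thin and its motions are large by design.
* The registration metric, optimizer and smoothing of commercial
  motion-estimation tools are undisclosed; this package documents its own
  choices and makes no equivalence claim.
* Only axis-aligned RAS grids are supported; oblique NIfTI orientations
  are rejected on load.
* The categorisation's middle-interval tie rule and the exact-test
  two-sided convention are documented choices among published variants.
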