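---
title: "Measuring nematode size and shape from brightfield images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nematode size and shape from brightfield images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemameter)
```

## The measurement model

A nematode lying on an agar surface, imaged in brightfield, appears as a
dark, elongated tube on a bright background. nemameter reduces each worm to
a one-dimensional description — a medial path with a radius profile
`r(s)` sampled along it — and derives every size measurement from that
description:

* **length** is the arclength of the medial path, tip to tip;
* **width** at a point is the length of the chord through that point
  orthogonal to the path, bounded by the worm's edges; the reported
  *middle width* is the width at half the arclength, and the *average
  width* is the mean over all interior samples;
* **volume** assumes only radial symmetry: each cross-section is taken to
  be a disc of radius `r(s)`, so the worm's volume is the solid of
  revolution
  $$V = \int_0^L \pi\, r(s)^2\, ds,$$
  approximated by sampling `r` at a fixed arclength interval `h` and
  summing conical frustums over consecutive samples:
  $$V \approx \sum_i \frac{\pi\,(s_{i+1}-s_i)}{3}
      \left(r_i^2 + r_i r_{i+1} + r_{i+1}^2\right).$$

The frustum sum is the solid-of-revolution analogue of the trapezoid rule:
it is exact for cylinders (constant `r`) and cones (linear `r`), and its
error for smooth profiles shrinks quadratically in `h`. This is the reason
volume is insensitive to the exact choice of `h` (below), and the reason
the estimate responds to tapering — unlike the classical *cylinder
approximation* $\pi (w_{mid}/2)^2 L$ from a single mid-body width, which
systematically overestimates any worm that is widest at its middle.

Radial symmetry is the model's one biological assumption. It is reasonable
for healthy worms resting on agar but not exact for, e.g., rolling mutants
mid-twist; no attempt is made to model asymmetric cross-sections.

## The processing chain

`run_pipeline()` applies, per image:

1. **Illumination flattening** (`subtract_background()`). Uneven
   illumination is modelled with Sternberg's rolling ball: the background
   is the surface traced by a ball of radius `ball_radius_px` rolled under
   the intensity landscape, computed as a grayscale morphological opening
   with a spherical-cap structuring function. The estimated background is
   replaced by its mean, so smooth gradients vanish while objects narrower
   than the ball survive. For brightfield input (`light_background =
   TRUE`) the image is inverted first and kept in the objects-bright
   orientation afterwards, which is what the thresholding step expects.
2. **Thresholding** (`minimum_threshold()`). The intensity histogram is
   smoothed repeatedly with a 3-point moving average until exactly two
   strict local maxima remain — one for background, one for worms — and
   the threshold is the valley between them (`y[t-1] > y[t] <= y[t+1]`,
   lowest count first, smallest `t` on ties). Images whose histogram never
   becomes bimodal (blank plates) are skipped with a logged reason.
3. **Candidate extraction** (`connected_components()`, `area_filter()`).
   Foreground pixels are grouped with 8-connectivity (background is
   implicitly 4-connected, the standard complementary pair), each
   component's outer contour is traced with the Moore boundary-following
   algorithm, and components outside `[area_min_px2, area_max_px2]` —
   specks, eggs, scratches — are discarded.
4. **Medial path** (`thin_mask()`, `prune_to_path()`, `smooth_path()`,
   `extend_to_edges()`). Each mask is thinned to a 1-px skeleton
   (Zhang-Suen topological thinning, connectivity preserving). Noise can
   leave side branches, so the skeleton's pixel graph — orthogonal steps
   weigh 1, diagonal steps $\sqrt 2$ — is pruned to its maximum-weight
   endpoint-to-endpoint path. The retained fraction of total skeleton
   length, the *prune ratio*, doubles as a quality filter
   (`prune_ratio_min`): heavily branched blobs are not worms. Skeletons
   containing a cycle are self-touching worms, which cannot be measured
   as a single tube; they are auto-failed rather than repaired. Finally
   the path is extended from both tips along its local tangent to the
   worm's edge, recovering the tip length that thinning retracts.
5. **Measurement** (`sample_radii()`, `measure_worm()`). Radii are sampled
   every `interval_px` along the path: the local tangent is a central
   difference over `extension_window_px` path points, and both normal
   directions are marched in 0.25-px steps to the mask edge. The radius is
   the mean of the two one-sided distances, which cancels small
   off-centering of the path; the width is their sum. The tips, which the
   extension step has placed on the contour, contribute explicit `r = 0`
   samples so the closing segments are cones. Pixel measurements convert
   to physical units through the image scale `s` in µm/px — lengths by
   `s`, volumes by `s³` — and volumes are reported in picoliters
   (1 pl = 1000 µm³).

Every stage is deterministic; two runs over the same inputs produce
byte-identical CSVs.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `ball_radius_px` | 50 | rolling-ball radius; must be well above the worm half-width and well below the illumination wavelength |
| `area_min_px2`, `area_max_px2` | 100, 10⁶ | candidate area filter |
| `prune_ratio_min` | 0.8 | minimum pruned/original skeleton length; rejects branched blobs, tolerates tip spurs |
| `interval_px` | 10 | radius sampling interval `h` |
| `extension_window_px` | 5 | path points in tangent fits (tips and normals) |
| `path_smooth_window` | 7 | moving-average window applied to the pruned path |

The sampling interval deserves comment. Too small an interval (~1 px)
samples the pixel quantization noise of the contour; too large an interval
(approaching half the worm) cannot follow the taper. Between 5 px and
roughly 10% of the worm's length the volume barely moves: on ten tapered
phantoms with ~396-px backbones, the mean per-worm CV of volume across
intervals 5–40 px is about 1.3% (`scripts/acceptance.R` recomputes this).
The default of 10 px sits comfortably inside that plateau.

## Numerical choices

* **Path smoothing.** A pixel-resolution skeleton is a staircase, and its
  chain-code length overestimates the underlying curve's length by an
  angle-dependent factor that we measured at up to +17% for oblique
  straight tubes — far outside the ~3% accuracy the rest of the chain
  supports. Averaging each path point with its neighbors (window
  `path_smooth_window`, shrinking symmetrically near the tips, endpoints
  fixed) converts the staircase into a subpixel polyline; length error
  drops below 0.5% at every orientation we tested, and measurements become
  rotation-invariant to within 2%. The window is small enough (7 px)
  that genuine worm curvature, with radii two orders of magnitude larger,
  is untouched.
* **Skeleton graph construction.** Connecting every pair of 8-adjacent
  skeleton pixels would create a weight-1/√2 triangle at every corner,
  making every curved skeleton cyclic. Diagonal edges are therefore added
  only when neither shared orthogonal neighbor is itself a skeleton pixel.
  With this standard minimal-connectivity rule, a clean skeleton is a
  tree, and a detected cycle really is a self-touching worm.
* **Longest path on the tree** is found exactly via pairwise weighted
  distances between degree-1 pixels; ties are broken toward the endpoint
  smallest in (row, col) order so output is reproducible.
* **Rolling ball at scale.** The opening is computed with a true
  spherical-cap structuring function. For radii above 15 px the image is
  first reduced (factor 2/4/8 by radius, block minima), the opening runs
  on the reduced grid with the cap's lateral extent scaled down but its
  depth unscaled, and the background is bilinearly upsampled — the
  standard speed optimization for this filter. Borders are replicate-padded
  so the estimate does not sag at corners. One intrinsic limitation is
  worth knowing: a ball of radius `R` penetrates the gap under an object
  of width `w` by $R - \sqrt{R^2 - (w/2)^2}$ (≈1 unit for a 20-px worm at
  `R = 50`, ≈3 units for a 33-px worm), which slightly reduces the
  object's contrast. Raise `ball_radius_px` when worms are wide relative
  to the default.
* **Threshold plateaus.** Averaged integer counts can tie exactly,
  transiently destroying a strict maximum; smoothing therefore continues
  until *exactly* two maxima remain (capped at 10,000 iterations) rather
  than stopping as soon as the count falls below three.
* **Degenerate inputs.** Empty masks, single-pixel skeletons, paths
  shorter than the tangent window, and profiles with fewer than two
  samples all produce explicit errors or zero-with-warning results, and
  the pipeline converts them into per-worm `auto-failed:` statuses rather
  than aborting a run.

## The phantom generator

Real calibration images for this instrument class are not distributable,
so validation rests on synthetic *phantoms* with analytic ground truth
(`phantom_spec()`, `render_phantom()`). A phantom is a tube around a
natural cubic spline backbone with a radius profile `r(u)` vanishing at
both tips; the default profile `r_mid · sin(πu)^0.4` gives the broad
mid-body and short taper of real larvae and adults. Rasterization follows
one unambiguous rule — a pixel is foreground iff its center lies within
`r(u*)` of the backbone, `u*` the nearest parameter at 0.25-px dense
sampling — and the truth (arclength, mid width, quadrature volume, exact
mask) is computed before imaging corruption is applied: a background of
configurable level, a smooth illumination ramp of chosen peak-to-peak
amplitude, and additive Gaussian noise under a mandatory seed.

Two stock geometries mirror the study conditions this class of instrument
is used in: `phantom_adult()` (length ≈ 720 µm, mid radius ≈ 30 µm, the
48-hour young-adult scale) and `phantom_l1()` (length ≈ 205 µm, mid radius
≈ 10 µm, the arrested-L1 scale). Default imaging corruption is a 30-unit
illumination ramp with noise sd 3 on a 140-unit worm/background contrast —
conservative relative to a well-adjusted stereomicroscope.

Phantoms emulate geometry, illumination bias and sensor noise. They do
**not** emulate defocus blur, the partial burial of L1 tips in agar,
internal intensity structure, motion, or touching worms. Passing the
phantom suite therefore demonstrates the geometric correctness and noise
robustness of the chain, not its behavior on every real-world image;
the pass/fail review sidecar (`review.csv`, `apply_review()`) remains the
guard against segmentation failures that only a human can judge.

On twenty noisy adult phantoms the pipeline recovers volume within 5%,
length within 3% and middle width within 10% of the analytic truth, and
measurements move by under 2% across 45° rotations of the same worm;
these checks run as part of the test suite.

## Population statistics

The `sizestats` functions reproduce the statistical procedures used with
this instrument's data:

* `sample_skewness()` / `excess_kurtosis()` — moment estimators
  ($g_1 = m_3/m_2^{3/2}$, $g_2 = m_4/m_2^2 - 3$) used to check the
  normality assumption behind t-tests on volume.
* `balanced_subsample_ttest()` — when a strain and its control have
  unequal totals, the larger pooled group is subsampled without
  replacement to the smaller's size; a two-sided equal-variance Student
  t-test is run per iteration (1000 by default), and the median p-value
  is Bonferroni-multiplied and capped at 1. Balancing is on total counts;
  per-replicate balancing would be an alternative reading, but pooled
  totals match the way replicates are merged before testing. The seed is
  a required argument and the subsample stream is private, so results are
  bit-reproducible and the caller's RNG is untouched.
* `compare_slopes()` — shape is summarized by the slope of width on
  length; two slopes are compared with $t = (b_1 - b_2)/SE_{diff}$, where
  the residual variance is pooled over both regressions and
  $df = n_1 + n_2 - 4$ (Zar's procedure). Exact fits (zero pooled
  residual) report `p` as the smallest positive double rather than zero.
* `power_sample_size()` — solves the two-sample, two-sided noncentral-t
  power equation
  $1-\beta = 1 - F_{nct}(t_{1-\alpha/2,\,2(n-1)};\, 2(n-1),\,
  (\delta/\sigma)\sqrt{n/2})$ for real `n` by bisection on [2, 10⁷]
  (tolerance 10⁻⁶). With σ at 21% of the mean — the observed sample CV of
  adult volume — α = 0.01 and power 0.8, detecting a 15% volume
  difference needs 46 worms per group and a 10% difference 103; both are
  computed live in the acceptance tests.

## Problem sizes used in validation

The shipped validation suite uses phantoms of 200–460 px backbone length,
ten worms for the interval-robustness summary, twenty worms for recovery
bounds, eight orientations for rotation invariance, 1000 random bimodal
histograms against the threshold oracle, and 200 random pixel trees
against the exhaustive path oracle — sizes chosen so the full suite
exercises every code path in about a minute on a laptop-class CPU while
keeping every tolerance meaningful.

## Known limitations

* Touching or self-intersecting worms are rejected, not untangled.
* Only the Minimum thresholding rule is built in; the configuration field
  exists so alternatives can be added.
* The scale table interpolates linearly between recorded zooms and
  refuses to extrapolate.
* Width is the sum of the two one-sided skeleton-to-edge distances;
  whether one-sided or two-sided distances are "the" width is a
  convention, and the two-sided choice is the robust one under slight
  path off-centering.
* JPEG input is accepted (stereomicroscope software often writes it) but
  never produced, because lossy output would break reproducibility.
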