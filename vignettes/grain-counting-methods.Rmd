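---
title: "Counting rice grains per panicle from images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting rice grains per panicle from images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Grain number per panicle (GN) is a yield component routinely measured in
rice breeding and agronomy, and counting it by hand is slow. When a
detached panicle is imaged on a dark light-absorbing background — either on
a flatbed scanner or with a camera — the grains are bright, elongated
objects, but they touch and overlap, so directly counting connected regions
of a segmented image undercounts badly. `paniclecount` implements a
counting approach that sidesteps the touching-grain problem entirely: it
does not try to separate individual grains, but predicts the count from
global pixel-fraction features of the segmented branch mask with a linear
model. Panicles are expected to be manually shaped before imaging, either
with primary branches spread apart ("Shape B") or detached from the stem
("Shape C"); unshaped tangles ("Shape A") are out of scope because no
image method resolves them reliably.

## Preprocessing

`preprocess_image()` turns a raw RGB image into a clean, stem-free binary
branch mask in five steps:

1. **Grayscale.** ITU-R BT.601 luma (0.299 R + 0.587 G + 0.114 B), rounded
   to integers. The conversion is configurable but fixed by default so
   every downstream count is reproducible.
2. **Otsu segmentation.** The threshold is found by exhaustive search over
   the 256 integer gray levels, maximizing the between-class variance
   $\sigma_b^2(t) = w_0 w_1 (\mu_0 - \mu_1)^2$; ties take the smallest
   threshold, making the operation deterministic. The panicle is bright on
   a near-black background, so foreground is `gray > t` (an `invert` flag
   covers the opposite polarity).
3. **Component denoising.** Connected components smaller than
   `denoise_min_area` (default 1000 px on the reference frame) are
   removed. Fabric speckles are below 100 px while a panicle occupies well
   over 100,000 px, so the threshold sits far from both; components with
   area **equal or above** the threshold are kept — the boundary case
   cannot arise in practice and the `>=` convention makes the filter
   deterministic.
4. **Stem removal.** The mask is opened with a disk structuring element:
   the discrete disk inscribed in a 5 × 5 window (21 pixels; the window
   minus its four corners), eroding three times and dilating three times by
   default. Total erosion depth is 6 px, which erases the 5–10 px stem and
   rachis but only nibbles the 30–50 px grains, which the dilations
   restore. The residual `denoised AND NOT opened` contains the stem plus
   thin erosion fringe; a second component filter (`stem_min_area`, default
   200 px) keeps only the actual stem pieces, and subtracting those gives
   the stem-free branch mask. All subtractions are set differences, so
   masks stay strictly 0/1, and `stemless AND stem` is empty by
   construction.
5. **RGB masking.** The original image is blacked out everywhere outside
   the stem-free mask.

Morphology treats everything outside the image frame as background, so
erosion shrinks foreground touching the border; component connectivity is
8-connected by default (diagonal contact merges) and configurable to 4.

### Scaling the pixel parameters

All pixel defaults above are tied to the 2480 × 3507 scanner frame. For
other resolutions `scaled_preprocess_config()` rescales them with the
linear scale $s = \sqrt{HW / (2480 \cdot 3507)}$: areas scale with $s^2$
and the total erosion depth with $s$ (at least one iteration). The
package's reference experiments run at 620 × 877 ($s = 0.25$), where this
gives a 62 px denoise filter, a 12 px stem filter and one erode/dilate
iteration — the same morphological regime at a quarter of the linear
resolution.

## Features

Three pixel fractions are extracted from the stem-free mask, each
normalized by the original image area $S_{im} = H \times W$:

- **Coverage degree** $CD = N_{cd} / S_{im}$: the fraction of image pixels
  covered by branches. Grain area per grain is roughly constant within a
  group, so coverage is nearly proportional to grain number — this is the
  feature that carries almost all of the counting signal.
- **Skeleton** $Sk = N_{sk} / S_{im}$: pixels of the one-pixel-wide
  medial skeleton, obtained by Zhang–Suen two-subiteration thinning. The
  skeleton tracks total elongated length rather than area.
- **Contour** $Co = N_{co} / S_{im}$: pixels of the inner boundary — a
  foreground pixel with at least one background 4-neighbor (the frame
  border counts as background).

Features are computed per connected component (primary branch or grain
cluster) and summed; because components are disjoint and both thinning and
the contour test are local to an 8-connected component, the summed counts
equal the whole-mask counts exactly, which the package asserts. The
per-branch table is kept for diagnostics.

Each feature is then min–max normalized with training-set extremes,
$CD' = (CD - CD_{min}) / (CD_{max} - CD_{min})$ and likewise $Sk'$, $Co'$.
Normalization statistics are fit per group (subspecies × device × shape),
matching the per-group counting models; values for unseen images may fall
outside $[0, 1]$ and are deliberately not clamped. Fitting refuses a
degenerate feature whose training range is zero.

## Counting models

`fit_count_model()` fits GN on any ordered subset of $(CD', Sk', Co')$
plus an intercept by ordinary least squares. The univariate $CD'$ model is
the recommended default: the multivariate model adds little and the extra
terms are strongly collinear with coverage. Predictions are rounded
half-away-from-zero (a deliberate, documented convention — plain
`round()` would round halves to even), and the reported integer count is
clamped at zero while the raw prediction is always returned unclamped; all
$R^2$/RMSE computations use unmodified values.

`printed_models()` ships the eight published multivariate models (two
subspecies × scanner/camera × Shape B/C), e.g. Indica, Scanner + Shape B:
$GN = 364.93\,CD' + 0.70\,Sk' - 3.90\,Co' + 2.801$. They expect features
normalized with the original training extremes, which are not published,
so the registry serves as a transcription reference and worked example
rather than a drop-in predictor.

`evaluate_model()` reports $R^2 = 1 - SS_{res}/SS_{tot}$, RMSE, and mean
per-image counting accuracy $\frac{100}{n}\sum_i (1 - |p_i - t_i| / t_i)$.
The accuracy definition (per-image relative accuracy, averaged) is a
package choice — published accuracy tables never state their formula — and
is isolated in this one function so it can be swapped. With constant truths
$R^2$ is undefined and reported as `NA` with a warning.

## Baselines

`count_components()` and `erosion_split_count()` implement the naive
counters the regression approach is motivated against. Component counting
is exact when grains are disjoint and undercounts as soon as they touch;
eroding before counting can split shallow contacts but leaves deep
overlaps merged and can erase small grains entirely. Both failure modes
are reproduced in the test suite on constructed fixtures and on synthetic
panicles with elevated overlap probability. The watershed and
corner-matching splitters are intentionally not implemented: they are
rejected alternatives, not part of the method.

## The synthetic panicle generator

`render_panicle()` draws annotated panicle images so the whole pipeline is
testable without any real image data. What it emulates, at the reference
frame and scaled by $s$ elsewhere:

- grains as filled rotated ellipses, 30–50 px wide with subspecies aspect
  ratio (Indica ≈ 3.5, long and slender; Japonica ≈ 2.2), bright
  (gray 140–230) with per-grain level jitter and mild Gaussian noise, in
  straw-yellow RGB;
- thin stems and branch rachides 5–10 px wide, slightly darker and
  greener; Shape C renders each branch detached, Shape B joins them to a
  common stem so the whole panicle is one connected structure;
- a near-black background (uniform gray 0–20) with optional fabric
  speckles under 100 px;
- optional 1–2 px awn hairlines, off by default.

Grains attach with the base of the ellipse at the rachis edge, like
spikelets on pedicels, at alternating sides of evenly spaced nodes. A
placement is collision-checked (including 8-adjacency, so grains never
merely touch by accident) and retried with fresh angles, node jitter and
side flips; with `overlap_prob = 0` this guarantees exactly `n_grains`
disjoint grain components. With `overlap_prob > 0` the stated fraction of
placements is deliberately slid against the previous grain to create
touching/overlapping pairs — the difficulty the counting method is
designed to tolerate. The default `overlap_prob = 0.1` reflects a shaped
B/C panicle with occasional contacts.

Branch count defaults to a uniform draw between `max(8, n_grains/20)` and
14: a primary branch holds at most about 20 grains, and beyond that
constraint branch number varies freely, so total stem/rachis area is
mostly count-independent clutter. This matters for the stem-removal
comparison: stems add coverage that carries no counting signal, so a model
fit on stem-bearing masks is noisier, and removing stems improves
accuracy. (Tying branch count deterministically to grain count would
instead make stem area a counting signal and invert that comparison.)

What the generator does **not** emulate: perspective and lens distortion,
uneven illumination, awn tangles, secondary-branch architecture, partially
filled or discolored grains, and the texture statistics of real husks.
Passing tests on synthetic data therefore demonstrate the internal
consistency and statistical behavior of the pipeline — segmentation,
morphology, feature extraction, model fit — not photometric robustness on
any particular real camera or scanner.

## Reference experiment and problem sizes

`run_count_experiment()` is the package's reference workflow: it renders a
synthetic dataset with counts uniform on 60–220, runs the full pipeline,
fits the normalizer and the $CD'$ model on a training split and scores
rounded predictions on a validation split, streaming one image at a time
so memory stays flat. The shipped configuration uses 160 training and 100
validation images at 620 × 877 px — small enough to run on a laptop CPU in
a few minutes, large enough for stable split statistics. Under these
defaults the validation $R^2$ exceeds 0.95 and mean counting accuracy
exceeds 96%; the acceptance script recomputes both from scratch.

## Numerical choices and degenerate inputs

- Otsu: exhaustive integer search, smallest-threshold tie-break; a
  constant image is an error ("degenerate histogram").
- Component filter: `>=` threshold convention; empty masks pass through.
- Erosion/dilation: zero iterations is the identity; structuring element
  diameter must be odd.
- Zhang–Suen thinning deletes isolated blobs smaller than about 3 × 3 px
  (the classic behavior); this is harmless after component denoising,
  where surviving components are grain-sized.
- `fit_normalizer()` requires at least two vectors and a nonzero range per
  feature; `fit_count_model()` rejects rank-deficient designs; constant
  counts fit cleanly (zero slopes, `NA` in-sample $R^2$).
- All randomness flows through explicit integer seeds; rendering,
  preprocessing and fitting are bit-reproducible given the same inputs and
  seeds.

## Limitations

The regression approach never identifies individual grains, so it cannot
localize them, and its coefficients are group-specific: a model fit for one
subspecies/device/shape combination does not transfer to another (pooled
models degrade noticeably). The printed-model registry cannot be applied
to new images without the original normalization extremes. And all
headline numbers quoted here are synthetic-data results at desk scale;
performance on real scanner or camera images depends on acquisition
quality that the generator does not model.
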